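# Delimited-text persistence for claims bundles. One CSV per entity,
# header row, ISO-8601 dates, empty field = missing; a plain-text manifest
# records table names, row counts, and the generating config hash. The truth
# table is written alongside the bundle but read back only on request --
# analysis stages never load it.

bundle_tables <- c("patients", "fills", "dx_claims", "proc_claims",
                   "encounters", "labs", "truth")

date_cols <- list(patients = "birth_date", fills = "issue_date",
                  dx_claims = "date", proc_claims = "date",
                  encounters = "date", labs = "date",
                  truth = c("index_date", "era_end", "event_date"))

#' Write a claims bundle to a directory of CSV tables
#'
#' @param bundle a `claims_bundle` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  epoch <- bundle$config$epoch
  manifest <- character()
  for (nm in bundle_tables) {
    tb <- data.table::copy(bundle[[nm]])
    for (dc in intersect(date_cols[[nm]], names(tb))) {
      data.table::set(tb, j = dc, value = day_to_date(tb[[dc]], epoch))
    }
    path <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(tb, path, na = "")
    manifest <- c(manifest, sprintf("%s\t%d", nm, nrow(tb)))
  }
  writeLines(c(sprintf("epoch\t%s", epoch),
               sprintf("config_hash\t%s", config_hash(bundle$config)),
               sprintf("seed\t%d", bundle$config$seed),
               manifest),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a claims bundle from a directory of CSV tables
#'
#' @param dir directory written by [write_bundle()].
#' @param epoch ISO date for day offset 0 (default: read from the manifest).
#' @param load_truth whether to load the simulation truth table. Analysis
#'   code must leave this `FALSE`; only test harnesses set it.
#' @return a `claims_bundle` (without the generating config; `truth` is
#'   `NULL` unless requested).
#' @export
read_bundle <- function(dir, epoch = NULL, load_truth = FALSE) {
  man_path <- file.path(dir, "manifest.txt")
  if (is.null(epoch)) {
    if (!file.exists(man_path)) {
      stop(sprintf("load error: no manifest.txt in '%s'", dir), call. = FALSE)
    }
    man <- utils::read.delim(man_path, header = FALSE,
                             col.names = c("key", "value"))
    epoch <- man$value[man$key == "epoch"][1]
  }
  out <- list()
  for (nm in setdiff(bundle_tables, if (load_truth) NULL else "truth")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      stop(sprintf("load error: table '%s' missing (%s)", nm, path),
           call. = FALSE)
    }
    char_cols <- list(
      patients = c("sex", "race"),
      fills = c("drug_code", "drug_group", "drug_class", "setting"),
      dx_claims = "code", proc_claims = "code", labs = "test_name",
      truth = c("eligible", "channel"))[[nm]]
    tb <- data.table::fread(path, colClasses =
                              stats::setNames(rep("character",
                                                  length(char_cols)),
                                              char_cols))
    for (dc in intersect(date_cols[[nm]], names(tb))) {
      data.table::set(tb, j = dc, value = date_to_day(tb[[dc]], epoch))
    }
    check_bundle_table(nm, tb)
    out[[nm]] <- tb
  }
  out$epoch <- epoch
  structure(out, class = "claims_bundle")
}

required_cols <- list(
  patients = c("patient_id", "sex", "race", "birth_date"),
  fills = c("patient_id", "drug_code", "drug_group", "drug_class",
            "issue_date", "days_supply", "setting"),
  dx_claims = c("patient_id", "code", "date"),
  proc_claims = c("patient_id", "code", "date"),
  encounters = c("patient_id", "date"),
  labs = c("patient_id", "test_name", "date", "value"),
  truth = c("patient_id", "eligible", "index_date", "event", "time_days")
)

check_bundle_table <- function(name, tb) {
  missing <- setdiff(required_cols[[name]], names(tb))
  if (length(missing)) {
    stop(sprintf("load error: table '%s' lacks column '%s'",
                 name, missing[1]), call. = FALSE)
  }
  invisible(tb)
}
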