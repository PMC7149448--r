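# Codesets: named groups of diagnosis codes, procedure codes, VA drug-class
# codes, and drug ingredients. All outcome, exclusion, and covariate
# definitions are driven by these lists so they stay configurable inputs.
# The shipped defaults are SYNTHETIC plausible members (the original study's
# supplementary code lists are not reproduced); any real analysis must load
# its own codeset CSV.

#' Default synthetic codesets
#'
#' Built-in codeset table with one row per (codeset, member). Members are
#' normalized: uppercase, dotted ICD-9-CM strings for diagnosis/procedure
#' codes, verbatim class codes (e.g. `AM200`) for VA drug classes, uppercase
#' ingredient names for drug ingredients.
#'
#' @return a `data.table` with columns `name`, `kind`, `member`.
#' @export
default_codesets <- function() {
  cs <- function(name, kind, members) {
    data.table::data.table(name = name, kind = kind, member = members)
  }
  cond <- list(
    hypertension             = "401.9",
    coronary_artery_disease  = "414.01",
    diabetes_mellitus        = "250.00",
    osteoarthritis           = "715.90",
    congestive_heart_failure = "428.0",
    chronic_kidney_disease   = "585.9",
    cerebrovascular_disease  = "437.9",
    unstable_angina          = "411.1",
    hemorrhoids              = "455.6",
    stable_angina            = "413.9",
    stroke                   = "434.91",
    myopathies               = "359.9",
    migraine_headache        = "346.90",
    diabetic_neuropathy      = "357.2",
    myocardial_infarction    = "410.90",
    hyperkalemia             = "276.7",
    fibromyalgia             = "729.1",
    parkinsons_disease       = "332.0",
    rheumatoid_arthritis     = "714.0",
    irritable_bowel_syndrome = "564.1",
    colitis                  = "558.9",
    gastroparesis            = "536.3",
    hyperparathyroidism      = "252.00",
    hypercalcemia            = "275.42",
    multiple_sclerosis       = "340",
    gi_perforation           = "569.83",
    rectal_prolapse          = "569.1",
    rectocele                = "618.04",
    megacolon                = "564.7",
    impaction                = "560.32",
    anal_fissure             = "565.0"
  )
  classes <- list(
    anticoagulants_bl110     = "BL110",
    antilipemic_cv350        = "CV350",
    beta_blockers_cv100      = "CV100",
    quinolones_am400         = "AM400",
    erythromycins_am200      = "AM200",
    antihistamines_ah000     = "AH000",
    genitourinary_gu000      = "GU000",
    insulin_hs501            = "HS501",
    androgens_hs100          = "HS100",
    antipsychotics_cn700     = "CN700",
    nsaid_ms102              = "MS102",
    topical_analgesics_de650 = "DE650",
    antigout_ms400           = "MS400"
  )
  data.table::rbindlist(c(
    lapply(names(cond), function(n) cs(n, "diagnosis", cond[[n]])),
    lapply(names(classes), function(n) cs(n, "drug_class", classes[[n]])),
    list(
      cs("revascularization_cabg", "procedure", "36.10"),
      cs("constipation_dx", "diagnosis", c("564.00", "564.01", "564.09")),
      cs("constipation_proc", "procedure", c("96.38", "96.39")),
      # synthetic subset of the classic malignancy ranges; configurable input
      cs("cancer", "diagnosis", c("153.3", "162.9", "174.9", "185", "233.0")),
      cs("opioid", "drug_ingredient",
         c("OXYCODONE", "HYDROCODONE", "MORPHINE", "TRAMADOL", "FENTANYL")),
      cs("laxative", "drug_class", c("GA108", "GA109", "GA110")),
      cs("constipating", "drug_ingredient",
         c("FERROUS SULFATE", "OXYBUTYNIN", "DIPHENHYDRAMINE", "AMITRIPTYLINE"))
    )
  ))
}

normalize_members <- function(x) toupper(trimws(x))

#' Read codesets from CSV
#'
#' Expects columns `name`, `kind`, `member` (one member per row). Members are
#' normalized (uppercase, trimmed); kinds must be one of `diagnosis`,
#' `procedure`, `drug_class`, `drug_ingredient`.
#'
#' @param path CSV file path.
#' @return validated codeset `data.table`.
#' @export
read_codesets <- function(path) {
  if (!file.exists(path)) {
    stop_config("codesets", sprintf("file does not exist: '%s'", path))
  }
  cs <- data.table::fread(path, colClasses = "character")
  need <- c("name", "kind", "member")
  if (!all(need %in% names(cs))) {
    stop_config("codesets", sprintf("CSV must have columns %s",
                                    paste(need, collapse = ", ")))
  }
  cs <- cs[, .(name = name, kind = kind, member = normalize_members(member))]
  check_codesets(cs)
  cs
}

#' Write codesets to CSV
#' @param codesets codeset table.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_codesets <- function(codesets, path) {
  data.table::fwrite(codesets[, .(name, kind, member)], path)
  invisible(path)
}

#' Validate a codeset table
#'
#' Checks that every codeset is nonempty with a single valid kind and that
#' constipating-medication ingredients are disjoint from every other drug
#' codeset (a constipating ingredient must never also contribute to a
#' standard drug-class covariate).
#'
#' @param codesets codeset table.
#' @return the table, invisibly; errors on violation.
#' @export
check_codesets <- function(codesets) {
  kinds <- c("diagnosis", "procedure", "drug_class", "drug_ingredient")
  bad <- setdiff(unique(codesets$kind), kinds)
  if (length(bad)) stop_config("codesets", sprintf("unknown kind '%s'", bad[1]))
  nk <- codesets[, data.table::uniqueN(kind), by = name]
  if (any(nk$V1 > 1)) {
    stop_config("codesets", sprintf("codeset '%s' has multiple kinds",
                                    nk[V1 > 1]$name[1]))
  }
  if (any(codesets$member == "")) stop_config("codesets", "has empty members")
  constip <- codesets[name == "constipating"]$member
  other_drug <- codesets[name != "constipating" &
                           kind %in% c("drug_class", "drug_ingredient")]$member
  overlap <- intersect(constip, other_drug)
  if (length(overlap)) {
    stop_config("codesets",
                sprintf("constipating ingredient '%s' also appears in another drug codeset",
                        overlap[1]))
  }
  invisible(codesets)
}

#' Members of one codeset
#' @param codesets codeset table.
#' @param name codeset name.
#' @return character vector of members; errors if the codeset is unknown.
#' @export
codeset_members <- function(codesets, name) {
  # base extraction on purpose: inside [.data.table the argument `name`
  # would be shadowed by the column of the same name
  m <- codesets$member[codesets$name == name]
  if (!length(m)) stop_config("codesets", sprintf("unknown codeset '%s'", name))
  m
}
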