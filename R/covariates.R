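# Baseline covariate construction over the 12-month pre-index window.
#
# Window semantics: baseline windows are closed, [index - window_days,
# index - 1]; day 0 (the index date) belongs to the exposure era and is
# never baseline. Medication exposure counts if any nominal covered day
# (issue .. issue + supply - 1) falls in the window; constipating-medication
# recency uses chained coverage from the era module.

#' Flag a single binary baseline covariate for one patient
#'
#' @param records data.frame of the patient's claims (`code`, `date`) for
#'   diagnosis/procedure codesets, or fills (`drug_code`/`drug_class`,
#'   `issue_date`, `days_supply`) for drug codesets.
#' @param codeset the rows of the codeset table for one codeset (columns
#'   `kind`, `member`).
#' @param index_date index day offset.
#' @param window_days lookback length (default 365).
#' @return logical: any qualifying record in `[index - window_days,
#'   index - 1]`.
#' @export
flag_covariate <- function(records, codeset, index_date, window_days = 365L) {
  rec <- data.table::as.data.table(records)
  kind <- unique(codeset$kind)
  if (length(kind) != 1L || !kind %in%
        c("diagnosis", "procedure", "drug_class", "drug_ingredient")) {
    stop_config("codeset", "must have exactly one known kind")
  }
  members <- codeset$member
  lo <- index_date - window_days
  hi <- index_date - 1L
  if (kind %in% c("diagnosis", "procedure")) {
    return(nrow(rec[code %in% members & date >= lo & date <= hi]) > 0L)
  }
  key <- if (kind == "drug_class") "drug_class" else "drug_code"
  hit <- rec[rec[[key]] %in% members &
               issue_date <= hi & issue_date + days_supply - 1L >= lo]
  nrow(hit) > 0L
}

#' Classify a patient's baseline laxative context
#'
#' @param laxative_eras era table (class-level) for the patient's laxative
#'   fills, built with the same gap rule as the opioid eras.
#' @param index_era one-row era table for the index opioid era.
#' @return list with logicals `prevalent` (a laxative era starts before the
#'   index date and covers it), `preventative` (a laxative era starts on era
#'   day 1, 2 or 3), `prior_year_any` (any laxative coverage in the prior
#'   year), `prior_not_prevalent` (prior-year use that is not prevalent).
#' @export
classify_laxative_context <- function(laxative_eras, index_era) {
  le <- data.table::as.data.table(laxative_eras)
  idx <- index_era$start_date[1]
  if (nrow(le) == 0L) {
    return(list(prevalent = FALSE, preventative = FALSE,
                prior_year_any = FALSE, prior_not_prevalent = FALSE))
  }
  prevalent <- any(le$start_date < idx & le$end_date >= idx)
  preventative <- any(le$start_date >= idx & le$start_date <= idx + 2L)
  prior_year_any <- any(le$start_date <= idx - 1L &
                          le$end_date >= idx - 365L)
  list(prevalent = prevalent, preventative = preventative,
       prior_year_any = prior_year_any,
       prior_not_prevalent = prior_year_any && !prevalent)
}

#' Assign the mutually exclusive constipating-medication window
#'
#' Based on the most recent chained coverage day of constipating medication
#' strictly before the index date: gap d = index - last covered day maps to
#' `days_30_to_1` (1 <= d <= 30), `days_60_to_31` (31 <= d <= 60),
#' `days_365_to_61` (61 <= d <= 365), else `none`.
#'
#' @param constipating_coverage integer vector of covered days, or a
#'   data.frame of intervals (`cov_start`, `cov_end`).
#' @param index_date index day offset.
#' @return one of `"days_30_to_1"`, `"days_60_to_31"`, `"days_365_to_61"`,
#'   `"none"`.
#' @export
assign_constipating_window <- function(constipating_coverage, index_date) {
  if (is.data.frame(constipating_coverage)) {
    cc <- data.table::as.data.table(constipating_coverage)
    cc <- cc[cov_start <= index_date - 1L]
    last <- if (nrow(cc)) max(pmin(cc$cov_end, index_date - 1L)) else NA_integer_
  } else {
    days <- constipating_coverage[constipating_coverage <= index_date - 1L]
    last <- if (length(days)) max(days) else NA_integer_
  }
  if (is.na(last)) return("none")
  d <- index_date - last
  if (d <= 30L) "days_30_to_1"
  else if (d <= 60L) "days_60_to_31"
  else if (d <= 365L) "days_365_to_61"
  else "none"
}

#' Average laboratory values over the pre-index year for one patient
#'
#' @param labs data.frame with `test_name`, `date`, `value`.
#' @param index_date index day offset.
#' @param window_days lookback (default 365).
#' @return named list: per test, the arithmetic mean of in-window values, or
#'   `NA` if none. Non-numeric values are skipped with a warning.
#' @export
average_labs <- function(labs, index_date, window_days = 365L) {
  lb <- data.table::as.data.table(labs)
  if (!is.numeric(lb$value)) {
    suppressWarnings(num <- as.numeric(lb$value))
    if (anyNA(num) && !all(is.na(num) == is.na(lb$value))) {
      warning(sprintf("%d non-numeric lab value(s) skipped",
                      sum(is.na(num) & !is.na(lb$value))))
    }
    lb[, value := num]
  }
  lb <- lb[!is.na(value) & date >= index_date - window_days &
             date <= index_date - 1L]
  out <- lb[, .(mean_value = mean(value)), by = test_name]
  stats::setNames(as.list(out$mean_value), out$test_name)
}

#' Build the full baseline covariate table for a cohort
#'
#' Vectorized construction of every baseline covariate: dictionary-driven
#' condition/procedure/drug-class flags, the laxative context, the
#' constipating-medication recency window, demographics, and pre-index lab
#' averages.
#'
#' @param cohort cohort table from [build_cohort()].
#' @param bundle the `claims_bundle`.
#' @param codesets codeset table.
#' @param window_days baseline lookback (default 365).
#' @param gap_days era gap parameter used for laxative/constipating eras.
#' @return `data.table` keyed by `patient_id` with `age_at_index`,
#'   `sex_female`, race dummies (White reference), one 0/1 column per
#'   dictionary covariate, `laxative_prevalent`,
#'   `laxative_prior_not_prevalent`, `laxative_preventative`,
#'   three `constip_*` window dummies, and `lab_*` columns (NA = missing).
#' @export
build_covariate_table <- function(cohort, bundle,
                                  codesets = default_codesets(),
                                  window_days = 365L, gap_days = 14L) {
  cohort <- data.table::as.data.table(cohort)
  out <- cohort[, .(patient_id, index_date, age_at_index,
                    sex_female = as.integer(sex == "F"),
                    race_african_american = as.integer(race == "african_american"),
                    race_unknown = as.integer(race == "unknown"),
                    race_asian_pacific = as.integer(race == "asian_pacific"),
                    race_american_indian = as.integer(race == "american_indian"))]
  data.table::setkey(out, patient_id)
  dx <- merge(data.table::as.data.table(bundle$dx_claims),
              cohort[, .(patient_id, index_date)], by = "patient_id")
  dx <- dx[date >= index_date - window_days & date <= index_date - 1L]
  pr <- merge(data.table::as.data.table(bundle$proc_claims),
              cohort[, .(patient_id, index_date)], by = "patient_id")
  pr <- pr[date >= index_date - window_days & date <= index_date - 1L]
  fl <- merge(data.table::as.data.table(bundle$fills),
              cohort[, .(patient_id, index_date)], by = "patient_id")

  defs <- covariate_defs()
  for (j in seq_len(nrow(defs))) {
    members <- codeset_members(codesets, defs$codeset[j])
    pids <- switch(defs$kind[j],
      diagnosis = dx[code %in% members]$patient_id,
      procedure = pr[code %in% members]$patient_id,
      drug_class = fl[drug_class %in% members &
                        issue_date <= index_date - 1L &
                        issue_date + days_supply - 1L >=
                          index_date - window_days]$patient_id)
    data.table::set(out, j = defs$covariate[j],
                    value = as.integer(out$patient_id %in% unique(pids)))
  }

  # laxative context from class-level laxative eras
  lax_classes <- codeset_members(codesets, "laxative")
  lax_fills <- fl[drug_class %in% lax_classes]
  lax_ctx <- data.table::data.table(
    patient_id = out$patient_id, laxative_prevalent = 0L,
    laxative_prior_not_prevalent = 0L, laxative_preventative = 0L)
  if (nrow(lax_fills)) {
    le <- build_all_drug_eras(lax_fills, gap_days = gap_days,
                              group_col = "drug_class")
    le <- merge(le, cohort[, .(patient_id, index_date)], by = "patient_id")
    ctx <- le[, .(
      prevalent = any(start_date < index_date & end_date >= index_date),
      preventative = any(start_date >= index_date &
                           start_date <= index_date + 2L),
      prior_year = any(start_date <= index_date - 1L &
                         end_date >= index_date - window_days)
    ), by = patient_id]
    ctx[, `:=`(laxative_prevalent = as.integer(prevalent),
               laxative_prior_not_prevalent =
                 as.integer(prior_year & !prevalent),
               laxative_preventative = as.integer(preventative))]
    lax_ctx <- merge(lax_ctx[, .(patient_id)],
                     ctx[, .(patient_id, laxative_prevalent,
                             laxative_prior_not_prevalent,
                             laxative_preventative)],
                     by = "patient_id", all.x = TRUE)
    for (cc in c("laxative_prevalent", "laxative_prior_not_prevalent",
                 "laxative_preventative")) {
      data.table::set(lax_ctx, which(is.na(lax_ctx[[cc]])), cc, 0L)
    }
  }
  out <- merge(out, lax_ctx, by = "patient_id")

  # constipating-medication recency from chained coverage
  constip_ing <- codeset_members(codesets, "constipating")
  cf <- fl[drug_code %in% constip_ing]
  out[, `:=`(constip_days_30_to_1 = 0L, constip_days_60_to_31 = 0L,
             constip_days_365_to_61 = 0L)]
  if (nrow(cf)) {
    cov <- coverage_intervals(cf[, .(patient_id, drug_group = "constipating",
                                     issue_date, days_supply)])
    cov <- merge(cov, cohort[, .(patient_id, index_date)], by = "patient_id")
    cov <- cov[cov_start <= index_date - 1L]
    rec <- cov[, .(d = min(index_date - pmin(cov_end, index_date - 1L))),
               by = patient_id]
    rec[, cat := data.table::fifelse(d <= 30L, "constip_days_30_to_1",
                 data.table::fifelse(d <= 60L, "constip_days_60_to_31",
                 data.table::fifelse(d <= 365L, "constip_days_365_to_61",
                                     "none")))]
    for (cc in c("constip_days_30_to_1", "constip_days_60_to_31",
                 "constip_days_365_to_61")) {
      data.table::set(out, j = cc,
                      value = as.integer(out$patient_id %in%
                                           rec[cat == cc]$patient_id))
    }
  }

  # pre-index lab averages, wide
  lb <- merge(data.table::as.data.table(bundle$labs),
              cohort[, .(patient_id, index_date)], by = "patient_id")
  lb <- lb[date >= index_date - window_days & date <= index_date - 1L]
  if (nrow(lb)) {
    lw <- data.table::dcast(
      lb[, .(mean_value = mean(value)), by = .(patient_id, test_name)],
      patient_id ~ test_name, value.var = "mean_value")
    data.table::setnames(lw, setdiff(names(lw), "patient_id"),
                         paste0("lab_", setdiff(names(lw), "patient_id")))
    out <- merge(out, lw, by = "patient_id", all.x = TRUE)
  }
  out[, index_date := NULL]
  data.table::setkey(out, patient_id)
  out[]
}

#' Prune rare covariates and high-missingness labs from a design table
#'
#' GI anatomical trauma member flags are OR-combined into a single
#' `gi_anatomical_trauma` column first; then binary covariates with
#' prevalence below `min_prevalence` are dropped unless named in
#' `keep_list`, and `lab_*` columns missing in `drop_labs_missing_ge` or
#' more of the cohort are dropped. Idempotent.
#'
#' @param design_table covariate table ([build_covariate_table()] output).
#' @param min_prevalence pruning threshold for binary covariates (default
#'   0.01).
#' @param keep_list covariate names exempt from prevalence pruning.
#' @param drop_labs_missing_ge lab missingness threshold (default 0.60).
#' @param gi_members member columns to aggregate (default
#'   [gi_trauma_members()]).
#' @return list with `table` (pruned) and `log` (`data.table` of every
#'   drop/keep decision: `column`, `type`, `stat`, `action`).
#' @export
prune_covariates <- function(design_table, min_prevalence = 0.01,
                             keep_list = default_keep_list(),
                             drop_labs_missing_ge = 0.60,
                             gi_members = gi_trauma_members()) {
  tb <- data.table::as.data.table(design_table)
  log_rows <- list()
  members <- intersect(gi_members, names(tb))
  if (length(members)) {
    agg <- as.integer(rowSums(tb[, ..members]) > 0L)
    tb[, gi_anatomical_trauma := agg]
    tb[, (members) := NULL]
    log_rows[[length(log_rows) + 1L]] <- data.table::data.table(
      column = "gi_anatomical_trauma", type = "aggregate",
      stat = mean(agg),
      action = sprintf("combined from %d member flags", length(members)))
  }
  known <- setdiff(keep_list, names(tb))
  if (length(known)) {
    stop_config("keep_list",
                sprintf("names absent column '%s'", known[1]))
  }
  fixed <- c("patient_id", "age_at_index")
  for (cc in setdiff(names(tb), fixed)) {
    v <- tb[[cc]]
    if (startsWith(cc, "lab_")) {
      fmiss <- mean(is.na(v))
      drop <- fmiss >= drop_labs_missing_ge
      log_rows[[length(log_rows) + 1L]] <- data.table::data.table(
        column = cc, type = "lab", stat = fmiss,
        action = if (drop) "dropped (missingness)" else "kept")
      if (drop) tb[, (cc) := NULL]
    } else if (all(v %in% c(0L, 1L))) {
      prev <- mean(v)
      drop <- prev < min_prevalence && !cc %in% keep_list
      log_rows[[length(log_rows) + 1L]] <- data.table::data.table(
        column = cc, type = "binary", stat = prev,
        action = if (drop) "dropped (rare)"
                 else if (prev < min_prevalence) "kept (keep list)"
                 else "kept")
      if (drop) tb[, (cc) := NULL]
    }
  }
  list(table = tb[], log = data.table::rbindlist(log_rows))
}
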