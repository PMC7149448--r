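# Drug exposure eras from fill/administration records.
#
# Semantics (closed day intervals, integer day offsets):
#   * Supply chaining ("stockpiling"): records are processed in issue-date
#     order; each record's coverage starts at max(issue_date, previous
#     coverage end + 1) and runs for days_supply days. Supply is never
#     truncated, only shifted, so total covered days always equals the sum of
#     days_supply. Inpatient administration days are days_supply = 1 records
#     and participate in the same recurrence.
#   * Gap bridging: maximal runs of covered days whose internal uncovered
#     gaps are all <= gap_days form one era; gap length between consecutive
#     covered intervals is (next start - previous end - 1).
#
# The sequential recurrence end_i = max(issue_i, end_{i-1} + 1) + s_i - 1
# collapses to the closed form end_i = S_i + cummax(issue_i - 1 - S_{i-1})
# with S the running sum of supply, which vectorizes over all patients at
# once; tests check it against a literal day-bitmap oracle.

era_core <- function(dt, gap_days) {
  # dt: data.table with columns pid, grp, issue, supply, setting
  data.table::setorder(dt, pid, grp, issue, supply, setting)
  dt[, `:=`(S = cumsum(as.numeric(supply))), by = .(pid, grp)]
  dt[, M := cummax(issue - 1 - (S - supply)), by = .(pid, grp)]
  dt[, cov_end := as.integer(S + M)]
  dt[, cov_start := as.integer(cov_end - supply + 1L)]
  dt[, gap := cov_start - data.table::shift(cov_end) - 1L, by = .(pid, grp)]
  dt[, era_id := cumsum(is.na(gap) | gap > gap_days), by = .(pid, grp)]
  dt
}

#' Build drug-exposure eras for one patient and one drug group
#'
#' Converts raw fill/administration records into continuous exposure eras
#' using supply chaining (a fill issued before the previous fill's supply is
#' exhausted is shifted forward, never truncated) and bridging of uncovered
#' gaps of at most `gap_days` days.
#'
#' @param fills data.frame/data.table of fill records for a single patient
#'   and a single drug group, with columns `patient_id`, `drug_group`,
#'   `issue_date` (integer day offset), `days_supply` (>= 1) and optionally
#'   `setting` (`outpatient`/`inpatient`; inpatient records must have
#'   `days_supply == 1`).
#' @param gap_days maximum bridgeable uncovered gap, in days (default 14).
#' @return a `data.table` of eras sorted by `start_date` with columns
#'   `patient_id`, `drug_group`, `start_date`, `end_date` (closed interval),
#'   `n_fills`, `source_settings`; zero rows for empty input.
#' @examples
#' f <- data.frame(patient_id = 1L, drug_group = "opioid",
#'                 issue_date = c(0L, 40L), days_supply = c(30L, 30L))
#' build_drug_eras(f)  # 10-day gap bridged: one era [0, 69]
#' @export
build_drug_eras <- function(fills, gap_days = 14L) {
  fills <- data.table::as.data.table(fills)
  if (nrow(fills) == 0L) return(empty_eras())
  if (gap_days < 0L) stop("gap_days must be >= 0", call. = FALSE)
  if (data.table::uniqueN(fills$patient_id) > 1L) {
    stop("build_drug_eras expects fills for a single patient", call. = FALSE)
  }
  if (data.table::uniqueN(fills$drug_group) > 1L) {
    stop("build_drug_eras expects fills for a single drug group", call. = FALSE)
  }
  check_fills(fills)
  eras <- build_all_drug_eras(fills, gap_days = gap_days, group_col = "drug_group")
  data.table::setorder(eras, start_date)
  eras[]
}

#' Build eras for many patients and groups at once
#'
#' Vectorized version of [build_drug_eras()] grouping by patient and by
#' `group_col` (the coarse `drug_group`, or `drug_class` for class-level
#' laxative eras).
#'
#' @param fills fill table (any number of patients/groups).
#' @param gap_days maximum bridgeable gap in days.
#' @param group_col column defining the era-group key (default `drug_group`).
#' @return era `data.table` (`patient_id`, `drug_group`, `start_date`,
#'   `end_date`, `n_fills`, `source_settings`), keyed by patient and start.
#' @export
build_all_drug_eras <- function(fills, gap_days = 14L, group_col = "drug_group") {
  fills <- data.table::as.data.table(fills)
  if (nrow(fills) == 0L) return(empty_eras())
  check_fills(fills)
  dt <- data.table::data.table(
    pid = fills$patient_id,
    grp = fills[[group_col]],
    issue = as.integer(fills$issue_date),
    supply = as.integer(fills$days_supply),
    setting = if ("setting" %in% names(fills)) fills$setting else "outpatient"
  )
  dt <- era_core(dt, gap_days)
  eras <- dt[, .(
    start_date = min(cov_start),
    end_date = max(cov_end),
    n_fills = .N,
    source_settings = paste(sort(unique(setting)), collapse = "+")
  ), by = .(patient_id = pid, drug_group = grp, era_id)]
  eras[, era_id := NULL]
  data.table::setorder(eras, patient_id, drug_group, start_date)
  eras[]
}

#' Chained coverage intervals (pre-bridging)
#'
#' Returns the per-record covered day intervals after supply chaining but
#' before gap bridging; used e.g. to locate the most recent covered day of
#' constipating medication before an index date.
#'
#' @inheritParams build_all_drug_eras
#' @return `data.table` with `patient_id`, `drug_group`, `cov_start`,
#'   `cov_end` (closed intervals, disjoint within a group).
#' @export
coverage_intervals <- function(fills, group_col = "drug_group") {
  fills <- data.table::as.data.table(fills)
  if (nrow(fills) == 0L) {
    return(data.table::data.table(patient_id = integer(), drug_group = character(),
                                  cov_start = integer(), cov_end = integer()))
  }
  check_fills(fills)
  dt <- data.table::data.table(
    pid = fills$patient_id, grp = fills[[group_col]],
    issue = as.integer(fills$issue_date),
    supply = as.integer(fills$days_supply),
    setting = if ("setting" %in% names(fills)) fills$setting else "outpatient"
  )
  dt <- era_core(dt, gap_days = 0L)
  dt[, .(patient_id = pid, drug_group = grp, cov_start, cov_end)]
}

empty_eras <- function() {
  data.table::data.table(patient_id = integer(), drug_group = character(),
                         start_date = integer(), end_date = integer(),
                         n_fills = integer(), source_settings = character())
}

check_fills <- function(fills) {
  if (any(fills$days_supply < 1L)) {
    stop("days_supply must be >= 1 for every fill", call. = FALSE)
  }
  if ("setting" %in% names(fills) &&
      any(fills$setting == "inpatient" & fills$days_supply != 1L)) {
    stop("inpatient administration records must have days_supply == 1",
         call. = FALSE)
  }
  invisible(fills)
}

#' Select the qualifying index opioid era for one patient
#'
#' Returns the earliest era that (a) lasts at least `min_duration_days`
#' (closed-interval length `end - start + 1`), (b) starts inside
#' `[study_start, study_end]`, and (c) has no opioid coverage day in the
#' washout window `[start - washout_days, start - 1]`. The selected era's
#' start date is the patient's index date. Returns `NULL` when no era
#' qualifies (the patient is excluded).
#'
#' @param eras era table for the opioid group of a single patient, from
#'   [build_drug_eras()].
#' @param study_start,study_end day-offset bounds for eligible index dates.
#' @param min_duration_days minimum era length in days (default 30).
#' @param washout_days opioid-free lookback required before the index
#'   (default 365).
#' @param all_opioid_coverage optional `data.table` of opioid coverage
#'   intervals (`cov_start`, `cov_end`); defaults to the eras themselves
#'   (era boundary days are always covered days, so era intervals are an
#'   exact proxy for pre-index coverage).
#' @return a one-row era `data.table`, or `NULL`.
#' @export
select_index_era <- function(eras, study_start, study_end,
                             min_duration_days = 30L, washout_days = 365L,
                             all_opioid_coverage = NULL) {
  eras <- data.table::as.data.table(eras)
  if (nrow(eras) == 0L) return(NULL)
  stopifnot(study_start <= study_end)
  data.table::setorder(eras, start_date)
  cov <- if (is.null(all_opioid_coverage)) {
    eras[, .(cov_start = start_date, cov_end = end_date)]
  } else {
    data.table::as.data.table(all_opioid_coverage)
  }
  for (i in seq_len(nrow(eras))) {
    s <- eras$start_date[i]; e <- eras$end_date[i]
    if ((e - s + 1L) < min_duration_days) next
    if (s < study_start || s > study_end) next
    in_washout <- cov$cov_end >= s - washout_days & cov$cov_start <= s - 1L
    if (any(in_washout)) next
    return(eras[i])
  }
  NULL
}

#' Vectorized index-era selection across patients
#'
#' Same rule as [select_index_era()] applied per patient; prior opioid
#' coverage reduces to the previous era's end because one patient's eras are
#' disjoint and ordered.
#'
#' @param eras era table for the opioid group (any number of patients).
#' @inheritParams select_index_era
#' @return one index era row per qualifying patient.
#' @export
select_index_eras_all <- function(eras, study_start, study_end,
                                  min_duration_days = 30L, washout_days = 365L) {
  eras <- data.table::copy(eras)
  data.table::setorder(eras, patient_id, start_date)
  eras[, prev_end := data.table::shift(end_date), by = patient_id]
  eras[, ok := (end_date - start_date + 1L) >= min_duration_days &
         start_date >= study_start & start_date <= study_end &
         (is.na(prev_end) | prev_end < start_date - washout_days)]
  idx <- eras[ok == TRUE, .SD[1L], by = patient_id]
  idx[, c("prev_end", "ok") := NULL]
  idx[]
}
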