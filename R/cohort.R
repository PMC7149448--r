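# Cohort assembly: inclusion/exclusion criteria applied in a fixed order,
# with an attrition report recording the patients remaining after each step.
#
# Pipeline order: (1) any opioid era; (2) qualifying index era (>= 30
# continuous days, start inside the study window, 12-month opioid washout);
# (3) age >= 65 at index; (4) continuity of care (>= 1 encounter per year in
# the 24 months pre-index); (5) no cancer (< 2 cancer claims in the pre-index
# year).

#' Continuity-of-care check for one patient
#'
#' TRUE iff there is at least one encounter in each of the two pre-index
#' year blocks: `[index - 365, index - 1]` and `[index - 730, index - 366]`
#' (closed windows).
#'
#' @param encounters integer vector of encounter day offsets.
#' @param index_date index day offset.
#' @return logical scalar.
#' @export
assess_continuity <- function(encounters, index_date) {
  e <- as.integer(encounters)
  any(e >= index_date - 365L & e <= index_date - 1L) &&
    any(e >= index_date - 730L & e <= index_date - 366L)
}

#' Cancer exclusion check for one patient
#'
#' TRUE (exclude) iff the patient has at least two claims whose code is in
#' the cancer codeset dated within `[index - 365, index - 1]`. Claim records
#' are counted as-is by default (two same-day claims for the same code count
#' separately); set `distinct_days = TRUE` to count distinct claim days.
#'
#' @param dx_claims data.frame with `code` and `date` columns (one patient).
#' @param index_date index day offset.
#' @param cancer_codes character vector of normalized cancer codes.
#' @param distinct_days count distinct claim days instead of claim records.
#' @return logical scalar: exclude the patient?
#' @export
apply_cancer_exclusion <- function(dx_claims, index_date, cancer_codes,
                                   distinct_days = FALSE) {
  dx <- data.table::as.data.table(dx_claims)
  hits <- dx[code %in% cancer_codes &
               date >= index_date - 365L & date <= index_date - 1L]
  n <- if (distinct_days) data.table::uniqueN(hits$date) else nrow(hits)
  n >= 2L
}

#' Build the analysis cohort and attrition report
#'
#' @param bundle a `claims_bundle` (simulated or read from disk).
#' @param codesets codeset table (needs a `cancer` codeset).
#' @param gap_days era gap-bridging parameter (default 14).
#' @param min_duration_days minimum index era length (default 30).
#' @param washout_days opioid-free pre-index requirement (default 365).
#' @param study_start,study_end day-offset window for eligible index dates.
#' @param cancer_distinct_days see [apply_cancer_exclusion()].
#' @return list with `cohort` (one row per included patient: `patient_id`,
#'   `index_date`, `era_end`, `era_len`, `age_at_index`, `sex`, `race`) and
#'   `attrition` (`data.table` of `criterion`, `n_remaining`; attribute
#'   `final_n`).
#' @export
build_cohort <- function(bundle, codesets = default_codesets(),
                         gap_days = 14L, min_duration_days = 30L,
                         washout_days = 365L,
                         study_start = 731L, study_end = 1795L,
                         cancer_distinct_days = FALSE) {
  pats <- data.table::as.data.table(bundle$patients)
  steps <- list(c("all_patients", nrow(pats)))

  opioid_ing <- codeset_members(codesets, "opioid")
  op_fills <- data.table::as.data.table(bundle$fills)[drug_code %in% opioid_ing]
  op_fills <- op_fills[, .(patient_id, drug_group = "opioid", issue_date,
                           days_supply, setting)]
  eras <- build_all_drug_eras(op_fills, gap_days = gap_days)
  steps <- c(steps, list(c("any_opioid_era",
                           data.table::uniqueN(eras$patient_id))))

  idx <- select_index_eras_all(eras, study_start, study_end,
                               min_duration_days, washout_days)
  steps <- c(steps, list(c("qualifying_index_era", nrow(idx))))

  cohort <- idx[, .(patient_id, index_date = start_date, era_end = end_date,
                    era_len = end_date - start_date + 1L)]
  cohort <- merge(cohort, pats, by = "patient_id")
  cohort[, age_at_index := completed_years(birth_date, index_date)]
  cohort <- cohort[age_at_index >= 65L]
  steps <- c(steps, list(c("age_ge_65", nrow(cohort))))

  enc <- data.table::as.data.table(bundle$encounters)
  enc <- merge(enc, cohort[, .(patient_id, index_date)], by = "patient_id")
  cont <- enc[, .(
    ok = any(date >= index_date - 365L & date <= index_date - 1L) &&
      any(date >= index_date - 730L & date <= index_date - 366L)
  ), by = patient_id]
  cohort <- cohort[patient_id %in% cont[ok == TRUE]$patient_id]
  steps <- c(steps, list(c("care_continuity", nrow(cohort))))

  cancer_codes <- codeset_members(codesets, "cancer")
  dx <- data.table::as.data.table(bundle$dx_claims)[code %in% cancer_codes]
  dx <- merge(dx, cohort[, .(patient_id, index_date)], by = "patient_id")
  dx <- dx[date >= index_date - 365L & date <= index_date - 1L]
  counts <- if (cancer_distinct_days) {
    dx[, .(n = data.table::uniqueN(date)), by = patient_id]
  } else {
    dx[, .(n = .N), by = patient_id]
  }
  excl <- counts[n >= 2L]$patient_id
  cohort <- cohort[!patient_id %in% excl]
  steps <- c(steps, list(c("no_cancer", nrow(cohort))))

  attrition <- data.table::data.table(
    criterion = vapply(steps, `[`, "", 1L),
    n_remaining = as.integer(vapply(steps, `[`, "", 2L)))
  if (is.unsorted(rev(attrition$n_remaining))) {
    stop("internal error: attrition counts are not nonincreasing",
         call. = FALSE)
  }
  data.table::setattr(attrition, "final_n", nrow(cohort))
  cohort[, birth_date := NULL]
  data.table::setorder(cohort, patient_id)
  list(cohort = cohort[], attrition = attrition)
}
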