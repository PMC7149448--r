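# Composite outcome ascertainment within the index opioid era.
#
# A constipation event during the era is any of:
#   (a) a constipation diagnosis claim dated inside the era;
#   (b) a constipation procedure claim dated inside the era;
#   (c) a new laxative initiation: a class-level laxative era *starting*
#       inside the index era on era day >= 4 (a laxative class already
#       active at era start chains into its existing era and so never
#       starts a new one; a class new to the patient always does).
# Laxative starts on era days 1-3 (index date = day 1) are preventative
# prophylaxis and are excluded from outcomes. The earliest remaining
# candidate wins; same-day ties resolve diagnosis > procedure > medication.
# Patients with no candidate are censored at the era end.

channel_priority <- c(diagnosis = 1L, procedure = 2L, medication = 3L)

#' Ascertain the composite constipation outcome for one patient
#'
#' @param index_era one-row era table (`start_date`, `end_date`) for the
#'   patient's index opioid era.
#' @param dx_claims,proc_claims the patient's claims (`code`, `date`).
#' @param laxative_eras class-level laxative era table for the patient,
#'   built with the same gap rule as the opioid eras.
#' @param codesets codeset table (needs `constipation_dx`,
#'   `constipation_proc`).
#' @return a one-row `data.table` (an OutcomeRecord): `event` (0/1),
#'   `time_days` (event day with index = day 1, or era length if censored),
#'   `channel` (`diagnosis`/`medication`/`procedure`/`none`), `event_date`,
#'   plus per-channel any-qualifying flags `any_diagnosis`, `any_medication`,
#'   `any_procedure`.
#' @export
ascertain_outcome <- function(index_era, dx_claims, proc_claims,
                              laxative_eras, codesets = default_codesets()) {
  s <- index_era$start_date[1]
  e <- index_era$end_date[1]
  dx_codes <- codeset_members(codesets, "constipation_dx")
  proc_codes <- codeset_members(codesets, "constipation_proc")
  dx <- data.table::as.data.table(dx_claims)
  pr <- data.table::as.data.table(proc_claims)
  le <- data.table::as.data.table(laxative_eras)

  cand <- list(
    data.table::data.table(
      date = dx[code %in% dx_codes & date >= s & date <= e]$date,
      channel = "diagnosis"),
    data.table::data.table(
      date = pr[code %in% proc_codes & date >= s & date <= e]$date,
      channel = "procedure"),
    data.table::data.table(
      date = if (nrow(le)) {
        le[start_date >= s + 3L & start_date <= e]$start_date
      } else integer(),
      channel = "medication")
  )
  cand <- data.table::rbindlist(cand)
  out <- data.table::data.table(
    event = 0L, time_days = e - s + 1L, channel = "none",
    event_date = NA_integer_,
    any_diagnosis = as.integer(nrow(cand[channel == "diagnosis"]) > 0L),
    any_procedure = as.integer(nrow(cand[channel == "procedure"]) > 0L),
    any_medication = as.integer(nrow(cand[channel == "medication"]) > 0L))
  if (nrow(cand)) {
    cand[, prio := channel_priority[channel]]
    data.table::setorder(cand, date, prio)
    out[, `:=`(event = 1L, time_days = cand$date[1] - s + 1L,
               channel = cand$channel[1], event_date = cand$date[1])]
  }
  out[]
}

#' Ascertain outcomes for a whole cohort (vectorized)
#'
#' Same rule as [ascertain_outcome()], applied to every cohort member by
#' joins. Claims dated outside the index era are ignored.
#'
#' @param cohort cohort table from [build_cohort()] (`patient_id`,
#'   `index_date`, `era_end`, `era_len`).
#' @param bundle the `claims_bundle`.
#' @param codesets codeset table.
#' @param gap_days era gap parameter for the laxative eras (default 14).
#' @return `data.table`, one OutcomeRecord row per cohort patient:
#'   `patient_id`, `event`, `time_days`, `channel`, `event_date`,
#'   `any_diagnosis`, `any_medication`, `any_procedure`.
#' @export
ascertain_outcomes_all <- function(cohort, bundle,
                                   codesets = default_codesets(),
                                   gap_days = 14L) {
  cohort <- data.table::as.data.table(cohort)
  key <- cohort[, .(patient_id, index_date, era_end)]
  dx_codes <- codeset_members(codesets, "constipation_dx")
  proc_codes <- codeset_members(codesets, "constipation_proc")
  lax_classes <- codeset_members(codesets, "laxative")

  dx <- merge(data.table::as.data.table(bundle$dx_claims)[code %in% dx_codes],
              key, by = "patient_id")
  dx <- dx[date >= index_date & date <= era_end,
           .(patient_id, date, channel = "diagnosis")]
  pr <- merge(
    data.table::as.data.table(bundle$proc_claims)[code %in% proc_codes],
    key, by = "patient_id")
  pr <- pr[date >= index_date & date <= era_end,
           .(patient_id, date, channel = "procedure")]

  lax_fills <- data.table::as.data.table(bundle$fills)[
    drug_class %in% lax_classes]
  md <- data.table::data.table(patient_id = integer(), date = integer(),
                               channel = character())
  if (nrow(lax_fills)) {
    le <- build_all_drug_eras(lax_fills, gap_days = gap_days,
                              group_col = "drug_class")
    le <- merge(le, key, by = "patient_id")
    md <- le[start_date >= index_date + 3L & start_date <= era_end,
             .(patient_id, date = start_date, channel = "medication")]
  }

  cand <- data.table::rbindlist(list(dx, pr, md))
  any_flags <- data.table::dcast(
    unique(cand[, .(patient_id, channel, hit = 1L)]),
    patient_id ~ channel, value.var = "hit", fill = 0L)
  for (cc in c("diagnosis", "medication", "procedure")) {
    if (!cc %in% names(any_flags)) any_flags[, (cc) := 0L]
  }
  data.table::setnames(any_flags, c("diagnosis", "medication", "procedure"),
                       c("any_diagnosis", "any_medication", "any_procedure"))

  cand[, prio := channel_priority[channel]]
  data.table::setorder(cand, patient_id, date, prio)
  first <- cand[, .SD[1L], by = patient_id]

  out <- merge(cohort[, .(patient_id, index_date, era_len, era_end)],
               first[, .(patient_id, event_date = date, channel)],
               by = "patient_id", all.x = TRUE)
  out <- merge(out, any_flags, by = "patient_id", all.x = TRUE)
  for (cc in c("any_diagnosis", "any_medication", "any_procedure")) {
    data.table::set(out, which(is.na(out[[cc]])), cc, 0L)
  }
  out[, event := as.integer(!is.na(event_date))]
  out[, time_days := data.table::fifelse(event == 1L,
                                         event_date - index_date + 1L,
                                         era_len)]
  out[, channel := data.table::fifelse(is.na(channel), "none", channel)]
  stopifnot(all(out$time_days >= 1L), all(out$time_days <= out$era_len))
  out[, .(patient_id, event, time_days, channel, event_date,
          any_diagnosis, any_medication, any_procedure)]
}

#' Tabulate outcome ascertainment channels
#'
#' Counts patients with any qualifying record per channel during the era
#' (channels are not mutually exclusive) and, separately, the distribution
#' of the earliest-event (winning) channel. Percentages are of the cohort
#' size, half-up to two decimals.
#'
#' @param outcomes outcome table from [ascertain_outcomes_all()] (needs the
#'   `any_*` columns).
#' @return list with `any_channel` and `first_channel` data.tables
#'   (`channel`, `n`, `pct`) and `n_cohort`.
#' @export
tabulate_channels <- function(outcomes) {
  oc <- data.table::as.data.table(outcomes)
  if (nrow(oc) == 0L) stop("empty cohort", call. = FALSE)
  n_coh <- nrow(oc)
  any_tab <- data.table::data.table(
    channel = c("diagnosis", "medication", "procedure"),
    n = c(sum(oc$any_diagnosis), sum(oc$any_medication),
          sum(oc$any_procedure)))
  any_tab[, pct := pct_of(n, n_coh)]
  first_tab <- oc[event == 1L, .(n = .N), by = channel]
  first_tab <- merge(
    data.table::data.table(channel = c("diagnosis", "medication",
                                       "procedure")),
    first_tab, by = "channel", all.x = TRUE)
  first_tab[is.na(n), n := 0L]
  first_tab[, pct := pct_of(n, n_coh)]
  list(any_channel = any_tab[], first_channel = first_tab[],
       n_cohort = n_coh)
}
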