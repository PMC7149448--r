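# Independent oracles and shared fixtures for the test suite.

# Brute-force era oracle: paints a day bitmap with a supply-stock counter
# (each day consumes one stocked day if any is available; arriving fills add
# their supply to the stock), then merges covered runs whose uncovered gaps
# are <= gap_days. Deliberately literal and loop-based; it must stay
# independent of the vectorized recurrence in the package.
oracle_eras <- function(fills, gap_days = 14L) {
  if (nrow(fills) == 0L) return(data.frame(start = integer(), end = integer()))
  lo <- min(fills$issue_date)
  hi <- max(fills$issue_date) + sum(fills$days_supply) + 1L
  covered <- logical(hi - lo + 1L)
  stock <- 0L
  for (day in lo:hi) {
    stock <- stock + sum(fills$days_supply[fills$issue_date == day])
    if (stock > 0L) {
      covered[day - lo + 1L] <- TRUE
      stock <- stock - 1L
    }
  }
  days <- which(covered) + lo - 1L
  brk <- c(TRUE, diff(days) > gap_days + 1L)
  era_id <- cumsum(brk)
  data.frame(start = tapply(days, era_id, min),
             end = tapply(days, era_id, max), row.names = NULL)
}

random_fill_set <- function(max_fills = 50L, horizon = 1000L,
                            max_supply = 90L) {
  n <- sample.int(max_fills, 1L)
  inpat <- runif(n) < 0.15
  data.table::data.table(
    patient_id = 1L, drug_group = "opioid",
    issue_date = sample.int(horizon, n, replace = TRUE),
    days_supply = ifelse(inpat, 1L,
                         sample.int(max_supply, n, replace = TRUE)),
    setting = ifelse(inpat, "inpatient", "outpatient"))
}

# Bundles and pipeline runs are expensive; cache per (n, seed) across files.
.fixture_cache <- new.env(parent = emptyenv())

get_test_bundle <- function(n = 4000L, seed = 11L) {
  key <- sprintf("bundle_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      simulate_cohort(sim_config(n_patients = n, seed = seed))
  }
  .fixture_cache[[key]]
}

# Small synthetic cohorts legitimately produce separation warnings for very
# rare covariates; the small-scale pipeline tests silence them.
quiet_run <- function(...) suppressWarnings(run_pipeline(...))

get_acceptance_run <- function(n = 50000L, seed = 1L) {
  key <- sprintf("run_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- run_pipeline(
      list(n_patients = n, seed = seed, n_boot = 0L))
  }
  .fixture_cache[[key]]
}

# Per-patient re-evaluation of the five cohort predicates, written as plain
# loops against the raw bundle tables (independent of build_cohort).
oracle_cohort_ids <- function(bundle, codesets = default_codesets(),
                              study_start = 731L, study_end = 1795L) {
  opioid_ing <- codeset_members(codesets, "opioid")
  cancer_codes <- codeset_members(codesets, "cancer")
  keep <- integer()
  for (pid in bundle$patients$patient_id) {
    fills <- bundle$fills[patient_id == pid & drug_code %in% opioid_ing]
    if (nrow(fills) == 0L) next
    er <- oracle_eras(fills)
    er <- er[order(er$start), , drop = FALSE]
    idx <- NULL
    for (i in seq_len(nrow(er))) {
      s <- er$start[i]
      if (er$end[i] - s + 1L < 30L) next
      if (s < study_start || s > study_end) next
      washout <- FALSE
      for (j in seq_len(nrow(er))) {
        if (j != i && er$end[j] >= s - 365L && er$start[j] <= s - 1L) {
          washout <- TRUE
        }
      }
      if (!washout) { idx <- s; break }
    }
    if (is.null(idx)) next
    birth <- bundle$patients$birth_date[bundle$patients$patient_id == pid]
    if (floor((idx - birth) / 365.25) < 65) next
    enc <- bundle$encounters$date[bundle$encounters$patient_id == pid]
    if (!assess_continuity(enc, idx)) next
    dxp <- bundle$dx_claims[patient_id == pid]
    if (apply_cancer_exclusion(dxp, idx, cancer_codes)) next
    keep <- c(keep, pid)
  }
  keep
}

# Literal product-limit computation for small fixtures.
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    d <- sum(times == ut[i] & events == 1)
    n_at <- sum(times >= ut[i])
    s <- s * (1 - d / n_at)
    surv[i] <- s
  }
  list(event_times = ut, survival = surv)
}
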