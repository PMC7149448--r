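# Simulation configuration: the stated world the synthetic claims emulate.
# Defaults encode the published cohort's marginal covariate prevalences and
# adjusted hazard ratios, the reported era-duration quantiles (median 30,
# IQR 30-51, max 1024 days), and realistic fill-stream noise; see the
# methods vignette for the rationale behind every value that the source
# tables do not pin down.

#' Create a simulation configuration
#'
#' @param n_patients number of patients to simulate (>= 1).
#' @param seed integer root seed; every random stage derives its own stream
#'   from it.
#' @param covariate_prevalences named numeric overrides (probabilities) for
#'   entries of `covariate_defs()$prevalence`.
#' @param log_hazard_ratios named numeric overrides/additions for the true
#'   log hazard ratios; covariates not named anywhere default to 0. See
#'   [default_log_hazard_ratios()].
#' @param baseline_daily_hazard constant baseline hazard per day in (0, 1);
#'   the event-time truth is exponential, `h(t) = h0 * exp(x'beta)`.
#' @param era_duration list with `min_days` (minimum/modal era length,
#'   default 30), `p_min` (probability of an era of exactly `min_days`,
#'   default 0.5), `mean_extra` (mean of the exponential tail beyond
#'   `min_days`, default 30) and `max_days` (cap, default 1024).
#' @param channel_mix named probabilities for the outcome ascertainment
#'   channel of a true event: `diagnosis`, `medication`, `procedure`;
#'   must sum to 1.
#' @param lab_params data.frame with columns `test`, `mean`, `sd`, `miss`
#'   (`miss` in [0, 0.6)); see [default_lab_params()].
#' @param fill_noise list: `gap_prob` (chance a refill is late), `max_gap`
#'   (longest late-refill gap, days, <= the era gap rule so eras stay
#'   intact), `early_refill_prob` and `max_overlap` (stockpiling),
#'   `inpatient_prob` (chance an era contains a 3-day inpatient stay).
#' @param demography list: `p_male`, `race_probs` (named, sums to 1),
#'   `age_mean`, `age_sd` (age at index, truncated normal, years).
#' @param laxative_mix named probabilities for mutually exclusive baseline
#'   laxative history: `prevalent` (supply crosses era day 1) and
#'   `prior_not_prevalent` (prior-year use ending before the index).
#' @param preventative_prob probability of a laxative started on era days
#'   1-3 (prophylaxis; never an outcome event).
#' @param constipating_mix named probabilities for the mutually exclusive
#'   recency of constipating-medication coverage: `days_30_to_1`,
#'   `days_60_to_31`, `days_365_to_61`.
#' @param ineligible named probabilities of patients constructed to fail one
#'   inclusion step: `short_era`, `washout`, `young`, `no_continuity`,
#'   `cancer`; the remainder is the intended-cohort fraction.
#' @param multi_era_prob probability a cohort patient has a second, later
#'   opioid era (only the first is analyzed).
#' @param epoch ISO date mapped to day offset 0.
#' @param study_start,study_end day-offset window for eligible index dates.
#' @param correlation reserved hook for a covariate correlation structure;
#'   only `NULL` (independent covariates) is implemented.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       covariate_prevalences = NULL,
                       log_hazard_ratios = NULL,
                       baseline_daily_hazard = 0.0025,
                       era_duration = list(min_days = 30L, p_min = 0.5,
                                           mean_extra = 30, max_days = 1024L),
                       channel_mix = c(diagnosis = 0.36, medication = 0.637,
                                       procedure = 0.003),
                       lab_params = default_lab_params(),
                       fill_noise = list(gap_prob = 0.15, max_gap = 14L,
                                         early_refill_prob = 0.20,
                                         max_overlap = 10L,
                                         inpatient_prob = 0.05),
                       demography = list(p_male = 0.9751,
                                         race_probs = default_race_probs(),
                                         age_mean = 76, age_sd = 7.35),
                       laxative_mix = c(prevalent = 0.0618,
                                        prior_not_prevalent = 0.1841),
                       preventative_prob = 0.0491,
                       constipating_mix = c(days_30_to_1 = 0.8653,
                                            days_60_to_31 = 0.0224,
                                            days_365_to_61 = 0.0594),
                       ineligible = c(short_era = 0.04, washout = 0.03,
                                      young = 0.03, no_continuity = 0.03,
                                      cancer = 0.02),
                       multi_era_prob = 0.10,
                       epoch = "2006-01-01",
                       study_start = 731L,
                       study_end = 1795L,
                       correlation = NULL) {
  defs <- covariate_defs()
  prev <- stats::setNames(defs$prevalence, defs$covariate)
  if (!is.null(covariate_prevalences)) {
    unknown <- setdiff(names(covariate_prevalences), names(prev))
    if (length(unknown)) {
      stop_config("covariate_prevalences",
                  sprintf("names unknown covariate '%s'", unknown[1]))
    }
    prev[names(covariate_prevalences)] <- covariate_prevalences
  }
  lhr <- default_log_hazard_ratios()
  if (!is.null(log_hazard_ratios)) {
    lhr[names(log_hazard_ratios)] <- log_hazard_ratios
  }
  cfg <- structure(list(
    n_patients = n_patients, seed = seed,
    covariate_prevalences = prev, log_hazard_ratios = lhr,
    baseline_daily_hazard = baseline_daily_hazard,
    era_duration = era_duration, channel_mix = channel_mix,
    lab_params = data.table::as.data.table(lab_params),
    fill_noise = fill_noise, demography = demography,
    laxative_mix = laxative_mix, preventative_prob = preventative_prob,
    constipating_mix = constipating_mix, ineligible = ineligible,
    multi_era_prob = multi_era_prob, epoch = epoch,
    study_start = as.integer(study_start), study_end = as.integer(study_end),
    correlation = correlation
  ), class = "sim_config")
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param config a `sim_config` object.
#' @return the config, invisibly returned on success; informative error
#'   naming the offending field otherwise.
#' @export
validate_sim_config <- function(config) {
  if (!is.numeric(config$n_patients) || length(config$n_patients) != 1 ||
      is.na(config$n_patients) || config$n_patients < 1) {
    stop_config("n_patients", "must be a positive integer (>= 1)")
  }
  check_prob(config$covariate_prevalences, "covariate_prevalences")
  h0 <- config$baseline_daily_hazard
  if (!is.numeric(h0) || h0 <= 0 || h0 >= 1) {
    stop_config("baseline_daily_hazard", "must lie in (0, 1)")
  }
  cm <- config$channel_mix
  need <- c("diagnosis", "medication", "procedure")
  if (!all(need %in% names(cm))) {
    stop_config("channel_mix", "must name diagnosis, medication, procedure")
  }
  check_prob(cm, "channel_mix")
  if (abs(sum(cm) - 1) > 1e-9) {
    stop_config("channel_mix", "must sum to 1 (within 1e-9)")
  }
  lp <- config$lab_params
  if (!all(c("test", "mean", "sd", "miss") %in% names(lp))) {
    stop_config("lab_params", "must have columns test, mean, sd, miss")
  }
  if (any(lp$miss < 0 | lp$miss >= 0.6)) {
    stop_config("lab_params", "missingness probabilities must lie in [0, 0.6)")
  }
  check_prob(config$laxative_mix, "laxative_mix")
  if (sum(config$laxative_mix) > 1) {
    stop_config("laxative_mix", "probabilities must sum to <= 1")
  }
  check_prob(config$preventative_prob, "preventative_prob")
  check_prob(config$constipating_mix, "constipating_mix")
  if (sum(config$constipating_mix) > 1) {
    stop_config("constipating_mix", "probabilities must sum to <= 1")
  }
  check_prob(config$ineligible, "ineligible")
  if (sum(config$ineligible) >= 1) {
    stop_config("ineligible", "probabilities must sum to < 1")
  }
  check_prob(config$multi_era_prob, "multi_era_prob")
  rp <- config$demography$race_probs
  check_prob(rp, "demography$race_probs")
  if (abs(sum(rp) - 1) > 1e-9) {
    stop_config("demography$race_probs", "must sum to 1")
  }
  if (config$study_start > config$study_end) {
    stop_config("study_start", "must be <= study_end")
  }
  if (!is.null(config$correlation)) {
    stop_config("correlation",
                "correlated covariates are not implemented (hook only)")
  }
  invisible(config)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  n_patients: %d   seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  baseline daily hazard: %g\n", x$baseline_daily_hazard))
  cat(sprintf("  binary covariates: %d (of which %d with nonzero log-HR)\n",
              length(x$covariate_prevalences),
              sum(names(x$log_hazard_ratios) %in%
                    names(x$covariate_prevalences))))
  cat(sprintf("  channel mix: dx %.3f / med %.3f / proc %.3f\n",
              x$channel_mix[["diagnosis"]], x$channel_mix[["medication"]],
              x$channel_mix[["procedure"]]))
  cat(sprintf("  intended-cohort fraction: %.2f\n", 1 - sum(x$ineligible)))
  invisible(x)
}

# Cheap deterministic rolling hash of a config (manifest provenance only).
config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "lab_params")]),
             collapse = "")
  s <- paste0(s, paste(unlist(config$lab_params), collapse = ","))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
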