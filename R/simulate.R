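# Synthetic claims generator.
#
# Produces raw claims tables with the statistical structure the analysis
# pipeline assumes, under a known proportional-hazards truth: every baseline
# covariate the cohort engine is supposed to reconstruct is drawn first and
# then *encoded* as claims/fills the engine can rediscover, and event times
# are drawn from h(t) = h0 * exp(x'beta) and routed to one of the three
# ascertainment channels. The truth table is written alongside the bundle but
# is never read by any analysis stage.

#' Simulate a synthetic claims bundle
#'
#' @param config a [sim_config()] object.
#' @return an object of class `claims_bundle`: a list of data.tables
#'   `patients`, `fills`, `dx_claims`, `proc_claims`, `encounters`, `labs`,
#'   `truth`, plus the `sim_config` used. All dates are integer day offsets
#'   from `config$epoch`; [write_bundle()] renders them as ISO-8601.
#' @examples
#' b <- simulate_cohort(sim_config(n_patients = 50, seed = 7))
#' names(b)
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- as.integer(config$n_patients)
  set.seed(make_seed(config$seed, 1L))

  ## ---- demographics and eligibility ------------------------------------
  dem <- config$demography
  elig_levels <- c("cohort", names(config$ineligible))
  elig_probs <- c(1 - sum(config$ineligible), unname(config$ineligible))
  eligible <- sample(elig_levels, n, replace = TRUE, prob = elig_probs)
  sex <- ifelse(stats::runif(n) < dem$p_male, "M", "F")
  race <- sample(names(dem$race_probs), n, replace = TRUE,
                 prob = unname(dem$race_probs))
  index_date <- sample(config$study_start:config$study_end, n, replace = TRUE)
  # truncated-normal age at index; intended-cohort patients >= 65 by design
  p_lo <- stats::pnorm((65.5 - dem$age_mean) / dem$age_sd)
  p_hi <- stats::pnorm((100 - dem$age_mean) / dem$age_sd)
  age <- dem$age_mean + dem$age_sd *
    stats::qnorm(stats::runif(n, p_lo, p_hi))
  age[eligible == "young"] <- stats::runif(sum(eligible == "young"), 55, 64.4)
  birth_date <- as.integer(index_date - round(age * 365.25))

  ## ---- baseline covariate draws ----------------------------------------
  defs <- covariate_defs()
  prev <- config$covariate_prevalences[defs$covariate]
  X <- matrix(0L, n, nrow(defs), dimnames = list(NULL, defs$covariate))
  for (j in seq_len(nrow(defs))) {
    X[, j] <- as.integer(stats::runif(n) < prev[[j]])
  }
  lax_levels <- c("none", names(config$laxative_mix))
  lax <- sample(lax_levels, n, replace = TRUE,
                prob = c(1 - sum(config$laxative_mix),
                         unname(config$laxative_mix)))
  preventative <- as.integer(stats::runif(n) < config$preventative_prob)
  cw_levels <- c("none", names(config$constipating_mix))
  constip <- sample(cw_levels, n, replace = TRUE,
                    prob = c(1 - sum(config$constipating_mix),
                             unname(config$constipating_mix)))
  derived <- cbind(
    laxative_prevalent = as.integer(lax == "prevalent"),
    laxative_prior_not_prevalent = as.integer(lax == "prior_not_prevalent"),
    laxative_preventative = preventative,
    constip_days_30_to_1 = as.integer(constip == "days_30_to_1"),
    constip_days_60_to_31 = as.integer(constip == "days_60_to_31"),
    constip_days_365_to_61 = as.integer(constip == "days_365_to_61"),
    sex_female = as.integer(sex == "F"),
    race_african_american = as.integer(race == "african_american"),
    race_unknown = as.integer(race == "unknown"),
    race_asian_pacific = as.integer(race == "asian_pacific"),
    race_american_indian = as.integer(race == "american_indian")
  )
  Xm <- cbind(X, derived)

  ## ---- era lengths ------------------------------------------------------
  ed <- config$era_duration
  L <- rep(ed$min_days, n)
  tail_draw <- stats::runif(n) >= ed$p_min
  extra <- pmin(ceiling(stats::rexp(n, 1 / ed$mean_extra)),
                ed$max_days - ed$min_days)
  L[tail_draw] <- ed$min_days + extra[tail_draw]
  short <- eligible == "short_era"
  L[short] <- sample(10:29, sum(short), replace = TRUE)
  L <- as.integer(L)

  ## ---- event times under the proportional-hazards truth -----------------
  beta <- config$log_hazard_ratios[colnames(Xm)]
  beta[is.na(beta)] <- 0
  names(beta) <- colnames(Xm)
  ev <- simulate_event_times(Xm, beta, config$baseline_daily_hazard, L,
                             seed = make_seed(config$seed, 2L))

  ## ---- route events to ascertainment channels ---------------------------
  events_in <- data.table::data.table(
    patient_id = seq_len(n), index_date = index_date,
    time_days = ev$time_days, follow_up = L
  )[ev$event_indicator == 1L]
  routed <- inject_ascertainment_records(events_in, config$channel_mix,
                                         seed = make_seed(config$seed, 3L))

  set.seed(make_seed(config$seed, 4L))

  ## ---- opioid fill streams ----------------------------------------------
  fills_op <- simulate_fill_streams(index_date, L, config)
  # washout violators: an opioid fill 200 days before the index
  w <- which(eligible == "washout")
  if (length(w)) {
    fills_op <- rbind(fills_op, data.table::data.table(
      patient_id = w, issue_date = index_date[w] - 200L,
      days_supply = 10L, setting = "outpatient"))
  }
  # second eras for some cohort patients (only the first era is analyzed)
  m <- which(eligible == "cohort" &
               stats::runif(n) < config$multi_era_prob)
  if (length(m)) {
    fills_op <- rbind(fills_op, data.table::data.table(
      patient_id = m,
      issue_date = index_date[m] + L[m] - 1L +
        sample(45:200, length(m), replace = TRUE),
      days_supply = sample(30:60, length(m), replace = TRUE),
      setting = "outpatient"))
  }
  opioid_ing <- codeset_members(default_codesets(), "opioid")
  fills_op[, `:=`(drug_code = sample(opioid_ing, .N, replace = TRUE),
                  drug_group = "opioid", drug_class = "CN101")]

  ## ---- baseline covariate records ----------------------------------------
  csets <- default_codesets()
  dx_rows <- list(); proc_rows <- list(); fill_rows <- list(fills_op)
  for (j in seq_len(nrow(defs))) {
    who <- which(X[, defs$covariate[j]] == 1L)
    if (!length(who)) next
    members <- codeset_members(csets, defs$codeset[j])
    day <- index_date[who] - sample(1:365, length(who), replace = TRUE)
    if (defs$kind[j] == "diagnosis") {
      dx_rows[[length(dx_rows) + 1L]] <- data.table::data.table(
        patient_id = who, code = sample(members, length(who), replace = TRUE),
        date = day)
    } else if (defs$kind[j] == "procedure") {
      proc_rows[[length(proc_rows) + 1L]] <- data.table::data.table(
        patient_id = who, code = sample(members, length(who), replace = TRUE),
        date = day)
    } else { # drug_class exposure in the pre-index year
      fill_rows[[length(fill_rows) + 1L]] <- data.table::data.table(
        patient_id = who, issue_date = day, days_supply = 30L,
        setting = "outpatient",
        drug_code = paste0(members[1], " ING"), drug_group = "other",
        drug_class = members[1])
    }
  }

  # constipating-medication coverage with configured recency
  constip_ing <- codeset_members(csets, "constipating")
  band <- list(days_30_to_1 = 1:30, days_60_to_31 = 31:60,
               days_365_to_61 = 61:360)
  for (cat in names(band)) {
    who <- which(constip == cat)
    if (!length(who)) next
    dlast <- sample(band[[cat]], length(who), replace = TRUE)
    fill_rows[[length(fill_rows) + 1L]] <- data.table::data.table(
      patient_id = who, issue_date = index_date[who] - dlast - 4L,
      days_supply = 5L, setting = "outpatient",
      drug_code = sample(constip_ing, length(who), replace = TRUE),
      drug_group = "constipating", drug_class = "XX000")
  }

  # baseline laxative history (class GA108) and prophylaxis (class GA110)
  who <- which(lax == "prevalent")
  if (length(who)) {
    fill_rows[[length(fill_rows) + 1L]] <- data.table::data.table(
      patient_id = who,
      issue_date = index_date[who] - sample(5:20, length(who), replace = TRUE),
      days_supply = 30L, setting = "outpatient", drug_code = "PSYLLIUM",
      drug_group = "laxative", drug_class = "GA108")
  }
  who <- which(lax == "prior_not_prevalent")
  if (length(who)) {
    fill_rows[[length(fill_rows) + 1L]] <- data.table::data.table(
      patient_id = who,
      issue_date = index_date[who] -
        sample(60:300, length(who), replace = TRUE),
      days_supply = 30L, setting = "outpatient", drug_code = "PSYLLIUM",
      drug_group = "laxative", drug_class = "GA108")
  }
  who <- which(preventative == 1L)
  if (length(who)) {
    fill_rows[[length(fill_rows) + 1L]] <- data.table::data.table(
      patient_id = who,
      issue_date = index_date[who] + sample(0:2, length(who), replace = TRUE),
      days_supply = 14L, setting = "outpatient", drug_code = "BISACODYL",
      drug_group = "laxative", drug_class = "GA110")
  }

  ## ---- cancer exclusion violators ---------------------------------------
  w <- which(eligible == "cancer")
  if (length(w)) {
    cancer_codes <- codeset_members(csets, "cancer")
    dx_rows[[length(dx_rows) + 1L]] <- data.table::data.table(
      patient_id = rep(w, 2L),
      code = sample(cancer_codes, 2L * length(w), replace = TRUE),
      date = rep(index_date[w], 2L) -
        sample(1:365, 2L * length(w), replace = TRUE))
  }

  ## ---- encounters (continuity of care) ----------------------------------
  enc <- data.table::data.table(
    patient_id = seq_len(n),
    date = index_date - sample(10:360, n, replace = TRUE))
  older <- which(eligible != "no_continuity")
  enc <- rbind(enc, data.table::data.table(
    patient_id = older,
    date = index_date[older] - sample(370:720, length(older), replace = TRUE)))

  ## ---- laboratory results (MAR missingness tilted on age) ----------------
  lp <- config$lab_params
  zage <- (age - dem$age_mean) / dem$age_sd
  shifts <- list(
    bicarbonate_co2 = -0.5 * X[, "diabetes_mellitus"],
    hemoglobin = -1.0 * X[, "chronic_kidney_disease"],
    creatinine = 0.4 * X[, "chronic_kidney_disease"],
    magnesium = rep(0, n)
  )
  lab_rows <- list(); truth_labs <- list()
  for (i in seq_len(nrow(lp))) {
    test <- lp$test[i]
    mu <- lp$mean[i] + (shifts[[test]] %||% rep(0, n))
    p_miss <- stats::plogis(stats::qlogis(lp$miss[i]) + 0.4 * zage)
    present <- which(stats::runif(n) >= p_miss)
    truth_labs[[paste0("lab_", test)]] <- mu
    if (!length(present)) next
    k <- sample(1:3, length(present), replace = TRUE)
    pid <- rep(present, k)
    lab_rows[[length(lab_rows) + 1L]] <- data.table::data.table(
      patient_id = pid, test_name = test,
      date = index_date[pid] - sample(1:365, length(pid), replace = TRUE),
      value = round(stats::rnorm(length(pid), mu[pid], lp$sd[i]), 3))
  }

  ## ---- assemble ----------------------------------------------------------
  fills <- data.table::rbindlist(fill_rows, use.names = TRUE)
  fills <- rbind(fills, routed$laxative_fills, use.names = TRUE)
  dx <- data.table::rbindlist(c(dx_rows, list(routed$dx_claims)),
                              use.names = TRUE)
  pr <- data.table::rbindlist(c(proc_rows, list(routed$proc_claims)),
                              use.names = TRUE)
  data.table::setorder(fills, patient_id, issue_date, drug_group, drug_code)
  data.table::setorder(dx, patient_id, date, code)
  data.table::setorder(pr, patient_id, date, code)
  data.table::setorder(enc, patient_id, date)
  labs <- data.table::rbindlist(lab_rows, use.names = TRUE)
  data.table::setorder(labs, patient_id, test_name, date)

  truth <- data.table::data.table(
    patient_id = seq_len(n), eligible = eligible, index_date = index_date,
    era_len = L, era_end = index_date + L - 1L,
    event = 0L, time_days = L, channel = "none",
    event_date = NA_integer_, eta = as.numeric(Xm %*% beta))
  if (nrow(routed$events)) {
    truth[routed$events$patient_id,
          `:=`(event = 1L, time_days = routed$events$time_days,
               channel = routed$events$channel,
               event_date = routed$events$event_date)]
  }
  truth <- cbind(truth,
                 data.table::as.data.table(Xm)[, lapply(.SD, as.integer)],
                 data.table::as.data.table(truth_labs))

  structure(list(
    patients = data.table::data.table(
      patient_id = seq_len(n), sex = sex, race = race,
      birth_date = birth_date),
    fills = fills[, .(patient_id, drug_code, drug_group, drug_class,
                      issue_date, days_supply, setting)],
    dx_claims = dx, proc_claims = pr, encounters = enc, labs = labs,
    truth = truth, config = config
  ), class = "claims_bundle")
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (nm in c("patients", "fills", "dx_claims", "proc_claims",
               "encounters", "labs", "truth")) {
    cat(sprintf("  %-12s %8d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Simulate event times from a proportional-hazards truth
#'
#' Draws a continuous exponential time with rate
#' `h0 * exp(x'beta)` per patient, discretizes to whole days (ceiling), and
#' censors at the patient's follow-up.
#'
#' @param covariates binary matrix (patients x covariates) with column names.
#' @param log_hazard_ratios numeric vector aligned with the matrix columns
#'   (same length; if named, names must match the column names).
#' @param baseline_daily_hazard constant baseline hazard per day.
#' @param follow_up_days integer vector (length 1 or n) of follow-up days,
#'   all >= 1.
#' @param seed integer seed.
#' @return list with `event_indicator` (0/1) and `time_days` (event day, or
#'   follow-up when censored; always >= 1).
#' @export
simulate_event_times <- function(covariates, log_hazard_ratios,
                                 baseline_daily_hazard, follow_up_days,
                                 seed = 1L) {
  X <- as.matrix(covariates)
  if (length(log_hazard_ratios) != ncol(X)) {
    stop("shape error: length(log_hazard_ratios) must equal ncol(covariates)",
         call. = FALSE)
  }
  if (!is.null(names(log_hazard_ratios)) && !is.null(colnames(X)) &&
      !identical(names(log_hazard_ratios), colnames(X))) {
    stop("shape error: coefficient names do not match covariate columns",
         call. = FALSE)
  }
  if (any(follow_up_days < 1L)) {
    stop("follow_up_days must be >= 1", call. = FALSE)
  }
  n <- nrow(X)
  follow_up_days <- as.integer(rep_len(follow_up_days, n))
  set.seed(seed)
  rate <- baseline_daily_hazard * exp(as.numeric(X %*% log_hazard_ratios))
  t_cont <- stats::rexp(n) / rate
  day <- pmax(1, ceiling(t_cont))
  event <- as.integer(day <= follow_up_days)
  list(event_indicator = event,
       time_days = as.integer(ifelse(event == 1L, day, follow_up_days)))
}

#' Route true events to ascertainment channels
#'
#' Each true event emits exactly one record: a constipation diagnosis claim,
#' a constipation procedure claim, or a new laxative fill (class `GA109`),
#' dated `index_date + time_days - 1`. Medication-channel events falling on
#' era days 1-3 are pushed to day 4 (so the generator never produces an
#' event the preventative-laxative carve-out would discard); when follow-up
#' is shorter than 4 days such an event is rerouted to the diagnosis channel
#' instead.
#'
#' @param events data.table with `patient_id`, `index_date`, `time_days`
#'   and optionally `follow_up` (defaults to unbounded).
#' @param channel_mix named probabilities (`diagnosis`, `medication`,
#'   `procedure`) summing to 1.
#' @param seed integer seed.
#' @param codesets codeset table supplying constipation codes.
#' @return list of data.tables: `events` (with final `channel`, `time_days`,
#'   `event_date`), `dx_claims`, `proc_claims`, `laxative_fills`.
#' @export
inject_ascertainment_records <- function(events, channel_mix, seed = 1L,
                                         codesets = default_codesets()) {
  check_prob(channel_mix, "channel_mix")
  if (abs(sum(channel_mix) - 1) > 1e-9) {
    stop_config("channel_mix", "must sum to 1 (within 1e-9)")
  }
  ev <- data.table::as.data.table(events)
  empty_claim <- data.table::data.table(patient_id = integer(),
                                        code = character(), date = integer())
  empty_fill <- data.table::data.table(
    patient_id = integer(), issue_date = integer(), days_supply = integer(),
    setting = character(), drug_code = character(), drug_group = character(),
    drug_class = character())
  if (nrow(ev) == 0L) {
    return(list(events = ev, dx_claims = empty_claim,
                proc_claims = empty_claim, laxative_fills = empty_fill))
  }
  if (!"follow_up" %in% names(ev)) ev[, follow_up := .Machine$integer.max]
  set.seed(seed)
  chs <- c("diagnosis", "medication", "procedure")
  ev[, channel := sample(chs, .N, replace = TRUE,
                         prob = unname(channel_mix[chs]))]
  ev[channel == "medication" & time_days <= 3L & follow_up < 4L,
     channel := "diagnosis"]
  ev[channel == "medication" & time_days <= 3L, time_days := 4L]
  ev[, event_date := index_date + time_days - 1L]

  dx_codes <- codeset_members(codesets, "constipation_dx")
  proc_codes <- codeset_members(codesets, "constipation_proc")
  dx <- ev[channel == "diagnosis",
           .(patient_id, code = sample(dx_codes, .N, replace = TRUE),
             date = event_date)]
  pr <- ev[channel == "procedure",
           .(patient_id, code = sample(proc_codes, .N, replace = TRUE),
             date = event_date)]
  lx <- ev[channel == "medication",
           .(patient_id, issue_date = event_date, days_supply = 14L,
             setting = "outpatient", drug_code = "POLYETHYLENE GLYCOL",
             drug_group = "laxative", drug_class = "GA109")]
  list(events = ev[, .(patient_id, index_date, time_days, channel,
                       event_date)],
       dx_claims = if (nrow(dx)) dx else empty_claim,
       proc_claims = if (nrow(pr)) pr else empty_claim,
       laxative_fills = if (nrow(lx)) lx else empty_fill)
}

# Opioid fill streams covering [index, index + L - 1] per patient: chains of
# ~30-day fills with occasional bridgeable late gaps (<= max_gap days),
# occasional early refills (stockpiling), and an optional 3-day inpatient
# stay encoded as unit administration days.
simulate_fill_streams <- function(index_date, L, config) {
  fn <- config$fill_noise
  n <- length(index_date)
  inpat <- stats::runif(n) < fn$inpatient_prob
  pos <- rep(0L, n)
  out <- list()
  wave <- 1L
  while (any(pos < L)) {
    act <- which(pos < L)
    g <- integer(length(act))
    if (wave > 1L) {
      can_gap <- (L[act] - pos[act]) > 20L
      do_gap <- can_gap & stats::runif(length(act)) < fn$gap_prob
      g[do_gap] <- sample(seq_len(fn$max_gap), sum(do_gap), replace = TRUE)
    }
    pos2 <- pos[act] + g
    is_inp <- wave == 2L & inpat[act] & g == 0L & (L[act] - pos2) >= 3L
    s <- ifelse(is_inp, 3L, pmin(30L, L[act] - pos2))
    issue <- pos2
    if (wave > 1L) {
      early <- !is_inp & g == 0L &
        stats::runif(length(act)) < fn$early_refill_prob
      back <- sample(seq_len(fn$max_overlap), length(act), replace = TRUE)
      issue[early] <- pmax(0L, pos2[early] - back[early])
    }
    out_ids <- act[!is_inp]
    if (length(out_ids)) {
      out[[length(out) + 1L]] <- data.table::data.table(
        patient_id = out_ids,
        issue_date = index_date[out_ids] + issue[!is_inp],
        days_supply = s[!is_inp], setting = "outpatient")
    }
    inp_ids <- act[is_inp]
    if (length(inp_ids)) {
      out[[length(out) + 1L]] <- data.table::data.table(
        patient_id = rep(inp_ids, each = 3L),
        issue_date = rep(index_date[inp_ids] + pos2[is_inp], each = 3L) +
          rep(0:2, times = length(inp_ids)),
        days_supply = 1L, setting = "inpatient")
    }
    pos[act] <- pos2 + s
    wave <- wave + 1L
  }
  data.table::rbindlist(out)
}
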