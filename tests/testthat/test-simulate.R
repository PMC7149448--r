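test_that("invalid configurations are rejected with the offending field", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(10, channel_mix = c(diagnosis = 0.5,
                                              medication = 0.4,
                                              procedure = 0.2)),
               "channel_mix")
  expect_error(sim_config(10, covariate_prevalences = c(hypertension = 1.2)),
               "covariate_prevalences")
  expect_error(sim_config(10, covariate_prevalences = c(nonexistent = 0.5)),
               "covariate_prevalences")
  expect_error(sim_config(10, lab_params = data.frame(
    test = "x", mean = 0, sd = 1, miss = 0.7)), "lab_params")
  expect_error(sim_config(10, ineligible = c(short_era = 0.9, washout = 0.2,
                                             young = 0, no_continuity = 0,
                                             cancer = 0)),
               "ineligible")
})

test_that("identical config and seed give identical bundles", {
  b1 <- simulate_cohort(sim_config(n_patients = 300, seed = 42))
  b2 <- simulate_cohort(sim_config(n_patients = 300, seed = 42))
  for (nm in c("patients", "fills", "dx_claims", "proc_claims",
               "encounters", "labs", "truth")) {
    expect_identical(as.data.frame(b1[[nm]]), as.data.frame(b2[[nm]]),
                     info = nm)
  }
  b3 <- simulate_cohort(sim_config(n_patients = 300, seed = 43))
  expect_false(identical(as.data.frame(b1$fills), as.data.frame(b3$fills)))
})

test_that("marginal covariate prevalences are calibrated", {
  b <- get_test_bundle(n = 20000L, seed = 5L)
  tr <- b$truth
  prev <- sim_config(1)$covariate_prevalences
  # spec example: hypertension within 3 binomial SEs at n = 20,000
  p <- prev[["hypertension"]]
  expect_lt(abs(mean(tr$hypertension) - p), 3 * sqrt(p * (1 - p) / 20000))
  # invariant: every configured covariate within 4 binomial SEs
  for (cc in names(prev)) {
    p <- prev[[cc]]
    tol <- 4 * sqrt(p * (1 - p) / 20000) + 1e-12
    expect_lt(abs(mean(tr[[cc]]) - p), max(tol, 1.5 / 20000))
  }
})

test_that("event times follow the exponential truth", {
  X <- matrix(0L, 50000, 1, dimnames = list(NULL, "z"))
  ev <- simulate_event_times(X, c(z = 0), 0.01, 10000L, seed = 2)
  expect_true(all(ev$time_days >= 1L))
  expect_true(all(ev$event_indicator == 1L))
  # exponential mean 1/h0 = 100; SE ~ 100/sqrt(n); allow discretization bias
  expect_lt(abs(mean(ev$time_days) - 100.5), 3 * 100 / sqrt(50000))

  # a log(2) coefficient halves the median event time
  X2 <- matrix(rep(0:1, each = 25000), ncol = 1,
               dimnames = list(NULL, "z"))
  ev2 <- simulate_event_times(X2, c(z = log(2)), 0.005, 100000L, seed = 3)
  m0 <- stats::median(ev2$time_days[X2 == 0])
  m1 <- stats::median(ev2$time_days[X2 == 1])
  expect_lt(abs(m1 / m0 - 0.5), 0.05)

  # censoring limit: negligible hazard, one day of follow-up
  ev3 <- simulate_event_times(X, c(z = 0), 1e-9, 1L, seed = 4)
  expect_true(all(ev3$event_indicator == 0L))
  expect_true(all(ev3$time_days == 1L))

  expect_error(simulate_event_times(X, c(0, 0), 0.01, 10L), "shape")
  expect_error(simulate_event_times(X, c(w = 0), 0.01, 10L), "shape")
})

test_that("ascertainment routing honours the mix and the day-4 shift", {
  ev <- data.table::data.table(patient_id = 1:500, index_date = 1000L,
                               time_days = sample(1:60, 500, TRUE),
                               follow_up = 60L)
  # degenerate mix: everything becomes a diagnosis claim
  r <- inject_ascertainment_records(ev, c(diagnosis = 1, medication = 0,
                                          procedure = 0), seed = 1)
  expect_equal(nrow(r$dx_claims), 500L)
  expect_equal(nrow(r$laxative_fills), 0L)
  expect_equal(r$events$event_date, ev$index_date + r$events$time_days - 1L)

  # early medication events land on era day 4, never days 1-3
  ev2 <- data.table::data.table(patient_id = 1:200, index_date = 1000L,
                                time_days = 2L, follow_up = 60L)
  r2 <- inject_ascertainment_records(ev2, c(diagnosis = 0, medication = 1,
                                            procedure = 0), seed = 1)
  expect_true(all(r2$events$time_days == 4L))
  expect_true(all(r2$laxative_fills$issue_date == 1003L))

  # multinomial channel counts within 3 binomial SEs of the configured mix
  mix <- c(diagnosis = 0.36, medication = 0.637, procedure = 0.003)
  evn <- data.table::data.table(patient_id = 1:20000, index_date = 1000L,
                                time_days = 30L, follow_up = 60L)
  rn <- inject_ascertainment_records(evn, mix, seed = 7)
  for (ch in names(mix)) {
    obs <- mean(rn$events$channel == ch)
    expect_lt(abs(obs - mix[[ch]]),
              3 * sqrt(mix[[ch]] * (1 - mix[[ch]]) / 20000) + 1e-9)
  }
})

test_that("truth events always have a matching in-era record", {
  b <- get_test_bundle(n = 2000L, seed = 9L)
  tr <- b$truth[event == 1L]
  csets <- default_codesets()
  dxc <- codeset_members(csets, "constipation_dx")
  prc <- codeset_members(csets, "constipation_proc")
  for (i in seq_len(nrow(tr))) {
    pid <- tr$patient_id[i]; ed <- tr$event_date[i]
    hit <- switch(tr$channel[i],
      diagnosis = nrow(b$dx_claims[patient_id == pid & date == ed &
                                     code %in% dxc]) > 0,
      procedure = nrow(b$proc_claims[patient_id == pid & date == ed &
                                       code %in% prc]) > 0,
      medication = nrow(b$fills[patient_id == pid & issue_date == ed &
                                  drug_class == "GA109"]) > 0)
    expect_true(hit, info = sprintf("patient %d channel %s", pid,
                                    tr$channel[i]))
    expect_true(ed >= tr$index_date[i] && ed <= tr$era_end[i])
  }
})

test_that("bundle round-trips through the CSV writer and reader", {
  b <- simulate_cohort(sim_config(n_patients = 150, seed = 21))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  back <- read_bundle(dir, load_truth = TRUE)
  for (nm in c("fills", "dx_claims", "encounters")) {
    a <- data.table::setorderv(data.table::copy(b[[nm]]),
                               names(b[[nm]])[1:2])
    z <- data.table::setorderv(data.table::copy(back[[nm]]),
                               names(b[[nm]])[1:2])
    expect_equal(as.data.frame(a), as.data.frame(z)[, names(a)], info = nm)
  }
  # truth is withheld unless explicitly requested
  no_truth <- read_bundle(dir)
  expect_null(no_truth$truth)
})
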