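test_that("Kaplan-Meier matches hand product-limit computation", {
  km <- km_estimate(c(5, 10), c(1, 0))
  expect_equal(km$event_times, 5)
  expect_equal(km$survival, 0.5)

  all_cens <- km_estimate(c(3, 8, 12), c(0, 0, 0))
  expect_length(all_cens$event_times, 0L)

  four <- km_estimate(c(2, 4, 6, 8), c(1, 1, 1, 1))
  expect_equal(four$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(four$at_risk, c(4, 3, 2, 1))

  expect_error(km_estimate(numeric(), integer()), "empty")

  # random <= 10-observation fixtures against the literal oracle
  set.seed(12)
  for (i in 1:200) {
    n <- sample(2:10, 1L)
    times <- sample(1:12, n, replace = TRUE)
    events <- rbinom(n, 1, 0.6)
    if (sum(events) == 0L) next
    got <- km_estimate(times, events)
    want <- oracle_km(times, events)
    expect_equal(got$event_times, want$event_times, info = i)
    expect_equal(got$survival, want$survival, tolerance = 1e-12, info = i)
  }
})

test_that("Cox fit: null recovery, log(2) recovery, concordance symmetry", {
  set.seed(7)
  n <- 4000L
  z <- rbinom(n, 1, 0.5)
  # null: true HR 1
  t0 <- pmax(1, ceiling(rexp(n, 0.02)))
  d0 <- data.table::data.table(z = z, time = pmin(t0, 50L),
                               event = as.integer(t0 <= 50L))
  f0 <- fit_cox(d0)
  expect_lt(abs(f0$table$coef), 3 * f0$table$se)

  # true HR 2 on an exponential truth
  t1 <- pmax(1, ceiling(rexp(n, 0.02 * exp(log(2) * z))))
  d1 <- data.table::data.table(z = z, time = pmin(t1, 50L),
                               event = as.integer(t1 <= 50L))
  f1 <- fit_cox(d1)
  expect_lt(abs(f1$table$coef - log(2)), 3 * f1$table$se)
  expect_equal(f1$table$hr, exp(f1$table$coef))
  expect_true(f1$table$ci_low <= f1$table$hr &
                f1$table$hr <= f1$table$ci_high)
  expect_gt(f1$c_index, 0.5)

  # concordance on the anti-sorted predictor mirrors around 1/2
  lp <- f1$fit$linear.predictors
  c_fwd <- concordance_index(d1$time, d1$event, lp)$c_index
  c_rev <- concordance_index(d1$time, d1$event, -lp)$c_index
  expect_equal(c_fwd + c_rev, 1, tolerance = 1e-10)

  expect_error(fit_cox(d1[event == 0L]), "events")
  d_na <- data.table::copy(d1)[1, z := NA_integer_]
  expect_error(fit_cox(d_na), "missing")
})

test_that("reporting filter applies the band, CI and alpha rules", {
  tb <- data.table::data.table(
    name = c("inside_band", "kept_high", "ci_crosses", "kept_low",
             "band_edge"),
    hr = c(1.05, 1.11, 0.80, 0.84, 1.10),
    ci_low = c(1.02, 1.05, 0.55, 0.77, 1.02),
    ci_high = c(1.08, 1.18, 1.15, 0.93, 1.19),
    p = c(0.001, 0.0005, 0.20, 0.0003, 0.001))
  kept <- filter_reportable(tb)
  expect_equal(kept$name, c("kept_high", "kept_low"))
  # idempotence
  expect_equal(filter_reportable(kept), kept)
  # alpha boundary: p = 0.05 is significant, p = 0.051 is not
  tb2 <- data.table::data.table(name = c("a", "b"), hr = c(1.5, 1.5),
                                ci_low = c(1.2, 1.2), ci_high = c(1.9, 1.9),
                                p = c(0.05, 0.051))
  expect_equal(filter_reportable(tb2)$name, "a")
})

test_that("cohort summary reproduces printed-percentage arithmetic", {
  co <- data.table::data.table(
    patient_id = 1:152904,
    sex = rep(c("M", "F"), c(149092L, 3812L)),
    laxative_prior_year = rep(c(1L, 0L), c(28143L, 152904L - 28143L)))
  s <- summarize_cohort(co)
  expect_equal(s$categorical[variable == "sex" & level == "M"]$pct, 97.51)
  expect_equal(s$categorical[variable == "sex" & level == "F"]$pct, 2.49)
  expect_equal(s$categorical[variable == "laxative_prior_year"]$pct, 18.41)

  single <- summarize_cohort(data.table::data.table(patient_id = 1L,
                                                    sex = "M"))
  expect_equal(single$categorical$pct, 100.00)
  expect_error(summarize_cohort(co[0L]), "empty")

  # race percentages from the published demographics table
  race_counts <- c(white = 112517L, african_american = 14672L,
                   unknown = 22785L, asian_pacific = 2130L,
                   american_indian = 800L)
  co2 <- data.table::data.table(
    patient_id = seq_len(sum(race_counts)),
    race = rep(names(race_counts), race_counts))
  s2 <- summarize_cohort(co2)
  got <- s2$categorical[variable == "race"]
  expect_equal(got[level == "white"]$pct, 73.59)
  expect_equal(got[level == "african_american"]$pct, 9.60)
  expect_equal(got[level == "unknown"]$pct, 14.90)
  expect_equal(got[level == "asian_pacific"]$pct, 1.39)
  expect_equal(got[level == "american_indian"]$pct, 0.52)
})

test_that("pooled HRs equal the single fit when nothing is missing", {
  set.seed(15)
  n <- 1500L
  z <- rbinom(n, 1, 0.3)
  t1 <- pmax(1, ceiling(rexp(n, 0.02 * exp(0.4 * z))))
  dd <- data.table::data.table(patient_id = 1:n, z = z,
                               lab_a = rnorm(n, 5),
                               time = pmin(t1, 60L),
                               event = as.integer(t1 <= 60L))
  single <- fit_cox(dd[, .(z, lab_a, time, event)])
  imps <- impute_pmm(dd, imputation_spec(seed = 5L))
  fits <- lapply(imps, function(d) fit_cox(d[, .(z, lab_a, time, event)]))
  pooled <- pool_cox_results(fits)
  expect_equal(pooled$hr, single$table$hr, tolerance = 1e-12)
  expect_equal(pooled$se_log, single$table$se, tolerance = 1e-12)
})

test_that("half-up rounding matches table conventions", {
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_equal(round_half_up(2.344, 2), 2.34)
  expect_equal(pct_of(1, 3), 33.33)
  expect_equal(pct_of(2, 3), 66.67)
  expect_equal(pct_of(125, 1000), 12.50)
})
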