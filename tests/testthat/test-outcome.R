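idx_era <- data.table::data.table(patient_id = 1L, drug_group = "opioid",
                                  start_date = 1000L, end_date = 1059L)
no_dx <- data.frame(code = character(), date = integer())
no_lax <- data.table::data.table(patient_id = integer(),
                                 drug_group = character(),
                                 start_date = integer(),
                                 end_date = integer())
lax_era <- function(s) data.table::data.table(
  patient_id = 1L, drug_group = "GA109", start_date = as.integer(s),
  end_date = as.integer(s + 13L))

test_that("single-channel events and the preventative carve-out", {
  # diagnosis on era day 10
  out <- ascertain_outcome(idx_era,
                           data.frame(code = "564.00", date = 1009L),
                           no_dx, no_lax)
  expect_equal(out$event, 1L)
  expect_equal(out$time_days, 10L)
  expect_equal(out$channel, "diagnosis")
  expect_equal(out$event_date, 1009L)

  # a laxative era starting on era day 2 is prophylaxis, not an outcome
  out <- ascertain_outcome(idx_era, no_dx, no_dx, lax_era(1001L))
  expect_equal(out$event, 0L)
  expect_equal(out$time_days, 60L)
  expect_equal(out$channel, "none")
  # era day 4 is the first eligible medication day
  out <- ascertain_outcome(idx_era, no_dx, no_dx, lax_era(1003L))
  expect_equal(out$event, 1L)
  expect_equal(out$time_days, 4L)
  expect_equal(out$channel, "medication")

  # records outside the era are ignored
  out <- ascertain_outcome(idx_era,
                           data.frame(code = "564.00", date = 1070L),
                           no_dx, no_lax)
  expect_equal(out$event, 0L)
})

test_that("earliest candidate wins; same-day ties use channel priority", {
  # laxative change on day 7, diagnosis on day 5: diagnosis wins
  out <- ascertain_outcome(idx_era,
                           data.frame(code = "564.01", date = 1004L),
                           no_dx, lax_era(1006L))
  expect_equal(out$channel, "diagnosis")
  expect_equal(out$time_days, 5L)
  expect_equal(out$any_medication, 1L)
  expect_equal(out$any_diagnosis, 1L)

  # same-day tie: diagnosis > procedure > medication
  out <- ascertain_outcome(idx_era,
                           data.frame(code = "564.00", date = 1010L),
                           data.frame(code = "96.38", date = 1010L),
                           lax_era(1010L))
  expect_equal(out$channel, "diagnosis")
  out <- ascertain_outcome(idx_era, no_dx,
                           data.frame(code = "96.38", date = 1010L),
                           lax_era(1010L))
  expect_equal(out$channel, "procedure")
})

test_that("channel tabulation reproduces printed-percentage arithmetic", {
  oc <- data.table::data.table(
    patient_id = 1:152904, event = 0L, time_days = 30L, channel = "none",
    event_date = NA_integer_, any_diagnosis = 0L, any_medication = 0L,
    any_procedure = 0L)
  oc[1:17810, any_medication := 1L]
  oc[1:6872, any_diagnosis := 1L]
  oc[1:43, any_procedure := 1L]
  tab <- tabulate_channels(oc)
  expect_equal(tab$any_channel[channel == "medication"]$pct, 11.65)
  expect_equal(tab$any_channel[channel == "diagnosis"]$pct, 4.49)
  expect_equal(tab$any_channel[channel == "procedure"]$pct, 0.03)
  expect_error(tabulate_channels(oc[0L]), "empty cohort")
})

test_that("vectorized ascertainment agrees with truth and the scalar rule", {
  b <- get_test_bundle(n = 4000L, seed = 11L)
  cb <- build_cohort(b)
  oc <- ascertain_outcomes_all(cb$cohort, b)
  tr <- b$truth[patient_id %in% cb$cohort$patient_id]
  data.table::setkey(tr, patient_id)
  data.table::setkey(oc, patient_id)
  expect_equal(oc$event, tr$event)
  ev <- tr$event == 1L
  expect_equal(oc$time_days[ev], tr$time_days[ev])
  expect_equal(oc$channel[ev], tr$channel[ev])
  expect_true(all(oc$time_days >= 1L))
  expect_true(all(oc$time_days <= cb$cohort$era_len))

  # scalar rule agrees on a sample of patients
  csets <- default_codesets()
  lax_classes <- codeset_members(csets, "laxative")
  set.seed(2)
  for (pid in sample(cb$cohort$patient_id, 30L)) {
    row <- cb$cohort[patient_id == pid]
    ie <- data.table::data.table(patient_id = pid, drug_group = "opioid",
                                 start_date = row$index_date,
                                 end_date = row$era_end)
    lf <- b$fills[patient_id == pid & drug_class %in% lax_classes]
    le <- if (nrow(lf)) {
      build_all_drug_eras(lf, group_col = "drug_class")
    } else no_lax
    got <- ascertain_outcome(ie, b$dx_claims[patient_id == pid],
                             b$proc_claims[patient_id == pid], le)
    expect_equal(got$event, oc[patient_id == pid]$event, info = pid)
    expect_equal(got$time_days, oc[patient_id == pid]$time_days, info = pid)
  }
})

test_that("removing laxative records can only decrease the event count", {
  b <- get_test_bundle(n = 4000L, seed = 11L)
  cb <- build_cohort(b)
  oc_full <- ascertain_outcomes_all(cb$cohort, b)
  b2 <- b
  b2$fills <- b$fills[drug_group != "laxative"]
  oc_cut <- ascertain_outcomes_all(cb$cohort, b2)
  expect_lte(sum(oc_cut$event), sum(oc_full$event))
  # and no patient gains an event or an earlier event date
  merged <- merge(oc_full[, .(patient_id, e1 = event, t1 = time_days)],
                  oc_cut[, .(patient_id, e2 = event, t2 = time_days)],
                  by = "patient_id")
  expect_true(all(merged$e2 <= merged$e1))
  expect_true(all(merged$t2 >= merged$t1))
})
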