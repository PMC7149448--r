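codesets <- default_codesets()

test_that("flag_covariate uses closed pre-index windows and drug coverage", {
  idx <- 1000L
  cs_htn <- codesets[name == "hypertension"]
  # boundary: a claim on index-1 is in the window, on the index day it is not
  expect_true(flag_covariate(data.frame(code = "401.9", date = idx - 1L),
                             cs_htn, idx))
  expect_false(flag_covariate(data.frame(code = "401.9", date = idx),
                              cs_htn, idx))
  expect_false(flag_covariate(data.frame(code = "401.9", date = idx - 366L),
                              cs_htn, idx))
  expect_true(flag_covariate(data.frame(code = "401.9", date = idx - 365L),
                             cs_htn, idx))
  # a fill issued before the window whose supply reaches into it still counts
  cs_ins <- codesets[name == "insulin_hs501"]
  f <- data.frame(drug_class = "HS501", drug_code = "HS501 ING",
                  issue_date = idx - 400L, days_supply = 60L)
  expect_true(flag_covariate(f, cs_ins, idx))     # covered to idx-341
  f$days_supply <- 30L
  expect_false(flag_covariate(f, cs_ins, idx))    # covered to idx-371
  expect_error(flag_covariate(f, data.frame(kind = "potion", member = "x"),
                              idx), "kind")
})

test_that("laxative context classification", {
  era <- function(s, e) data.table::data.table(
    patient_id = 1L, drug_group = "GA108", start_date = as.integer(s),
    end_date = as.integer(e), n_fills = 1L, source_settings = "outpatient")
  idx_era <- data.table::data.table(start_date = 1000L, end_date = 1059L)

  ctx <- classify_laxative_context(era(980, 1010), idx_era)
  expect_true(ctx$prevalent)
  expect_false(ctx$prior_not_prevalent)
  expect_true(ctx$prior_year_any)

  ctx <- classify_laxative_context(era(1002, 1020), idx_era)  # era day 3
  expect_true(ctx$preventative)
  expect_false(ctx$prevalent)
  ctx <- classify_laxative_context(era(1003, 1020), idx_era)  # era day 4
  expect_false(ctx$preventative)

  ctx <- classify_laxative_context(era(700, 800), idx_era)
  expect_true(ctx$prior_not_prevalent)
  expect_false(ctx$prevalent)

  ctx <- classify_laxative_context(era(1, 2)[0L], idx_era)
  expect_false(any(unlist(ctx)))
})

test_that("constipating window takes the most recent covered day", {
  idx <- 1000L
  expect_equal(assign_constipating_window(idx - 5L, idx), "days_30_to_1")
  expect_equal(assign_constipating_window(idx - 45L, idx), "days_60_to_31")
  expect_equal(assign_constipating_window(idx - 100L, idx), "days_365_to_61")
  expect_equal(assign_constipating_window(idx - 400L, idx), "none")
  expect_equal(assign_constipating_window(integer(), idx), "none")
  # recency argmax: coverage at -10 and -200 resolves to the 30-to-1 band
  expect_equal(assign_constipating_window(c(idx - 200L, idx - 10L), idx),
               "days_30_to_1")
  # interval form, clipped at index-1
  iv <- data.frame(cov_start = idx - 20L, cov_end = idx + 5L)
  expect_equal(assign_constipating_window(iv, idx), "days_30_to_1")
  # band boundaries
  expect_equal(assign_constipating_window(idx - 30L, idx), "days_30_to_1")
  expect_equal(assign_constipating_window(idx - 31L, idx), "days_60_to_31")
  expect_equal(assign_constipating_window(idx - 61L, idx), "days_365_to_61")
  expect_equal(assign_constipating_window(idx - 365L, idx), "days_365_to_61")
  expect_equal(assign_constipating_window(idx - 366L, idx), "none")
})

test_that("lab averaging filters to the window then takes the mean", {
  idx <- 1000L
  lb <- data.frame(test_name = "hemoglobin",
                   date = c(idx - 10L, idx - 20L), value = c(20, 30))
  expect_equal(average_labs(lb, idx)$hemoglobin, 25)
  out <- data.frame(test_name = "hemoglobin", date = idx - 400L, value = 9)
  expect_equal(length(average_labs(out, idx)), 0L)
  three <- data.frame(test_name = "hemoglobin",
                      date = c(idx - 10L, idx - 20L, idx - 400L),
                      value = c(20, 30, 999))
  expect_equal(average_labs(three, idx)$hemoglobin, 25)
  messy <- data.frame(test_name = "hemoglobin",
                      date = c(idx - 10L, idx - 20L),
                      value = c("20", "n/a"))
  expect_warning(got <- average_labs(messy, idx), "non-numeric")
  expect_equal(got$hemoglobin, 20)
})

test_that("pruning: threshold, keep list, lab missingness boundary", {
  n <- 1000L
  tb <- data.table::data.table(
    patient_id = 1:n,
    age_at_index = 70,
    common = rep(c(0L, 1L), c(n / 2, n / 2)),
    rare = rep(c(1L, 0L), c(5L, n - 5L)),                      # 0.5%
    irritable_bowel_syndrome = rep(c(1L, 0L), c(8L, n - 8L)),  # 0.8%
    hyperkalemia = rep(c(1L, 0L), c(8L, n - 8L)),
    race_asian_pacific = 0L, race_american_indian = 0L,
    lab_kept = c(rep(NA_real_, 599L), rnorm(401L)),            # 59.9%
    lab_dropped = c(rep(NA_real_, 600L), rnorm(400L))          # 60.0%
  )
  gi <- gi_trauma_members()
  for (g in gi) tb[, (g) := 0L]
  tb[1:4, (gi[1]) := 1L]
  p <- prune_covariates(tb)
  expect_false("rare" %in% names(p$table))
  expect_true("irritable_bowel_syndrome" %in% names(p$table))
  expect_true("lab_kept" %in% names(p$table))
  expect_false("lab_dropped" %in% names(p$table))
  # GI members collapse into one kept aggregate
  expect_true("gi_anatomical_trauma" %in% names(p$table))
  expect_false(any(gi %in% names(p$table)))
  expect_equal(sum(p$table$gi_anatomical_trauma), 4L)
  # idempotence
  p2 <- prune_covariates(p$table)
  expect_equal(names(p2$table), names(p$table))
  expect_equal(as.data.frame(p2$table), as.data.frame(p$table))
  # unknown keep-list names are a configuration error
  expect_error(prune_covariates(tb, keep_list = "no_such_column"),
               "keep_list")
})

test_that("constipating ingredients are disjoint from drug-class codesets", {
  expect_silent(check_codesets(default_codesets()))
  bad <- rbind(default_codesets(),
               data.table::data.table(name = "constipating",
                                      kind = "drug_ingredient",
                                      member = "HS501"))
  bad2 <- rbind(bad, data.table::data.table(name = "insulin_hs501",
                                            kind = "drug_class",
                                            member = "HS501"))
  expect_error(check_codesets(bad2), "constipating")
})

test_that("engine covariates reproduce the generator's truth exactly", {
  b <- get_test_bundle(n = 4000L, seed = 11L)
  cb <- build_cohort(b)
  covs <- build_covariate_table(cb$cohort, b)
  tr <- b$truth[patient_id %in% cb$cohort$patient_id]
  data.table::setkey(tr, patient_id)
  data.table::setkey(covs, patient_id)
  shared <- setdiff(intersect(names(covs), names(tr)), "patient_id")
  shared <- shared[!startsWith(shared, "lab_")]
  expect_gt(length(shared), 50L)
  for (cc in shared) {
    expect_equal(covs[[cc]], tr[[cc]], info = cc)
  }
  # window categories partition patients with any prior-year coverage
  withcov <- covs$constip_days_30_to_1 + covs$constip_days_60_to_31 +
    covs$constip_days_365_to_61
  expect_true(all(withcov <= 1L))
})
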