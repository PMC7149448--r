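# End-to-end pipeline: simulate/load claims -> opioid eras -> cohort ->
# covariates -> pruning -> outcomes -> PMM imputation -> pooled Cox ->
# reporting filter. All randomness flows from one root seed split per stage;
# the simulation truth table is never read by any stage here.

#' Default run configuration
#'
#' @param n_patients simulated cohort size (ignored when `bundle_dir` points
#'   at an existing bundle).
#' @param seed root seed for all stages.
#' @param out_dir output directory for the run artifacts (`NULL` = do not
#'   write files).
#' @return named list of every stage parameter with its default.
#' @export
default_run_config <- function(n_patients = 2000L, seed = 1L,
                               out_dir = NULL) {
  list(
    n_patients = n_patients, seed = seed, out_dir = out_dir,
    bundle_dir = NULL,          # read an existing bundle instead of simulating
    codesets_path = NULL,       # CSV; NULL = built-in defaults
    gap_days = 14L, min_duration_days = 30L, washout_days = 365L,
    window_days = 365L, study_start = 731L, study_end = 1795L,
    cancer_distinct_days = FALSE,
    min_prevalence = 0.01, drop_labs_missing_ge = 0.60,
    m_imputations = 5L, k_donors = 5L, max_iter = 10L,
    band_low = 0.9, band_high = 1.1, alpha = 0.05,
    n_boot = 200L
  )
}

#' Parse a key-value run configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; numeric-looking
#' values are coerced. Unknown keys are a configuration error.
#'
#' @param path text file path.
#' @return a full run-config list (file values over defaults).
#' @export
parse_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_config("config", sprintf("file does not exist: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- default_run_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      stop_config("config", sprintf("cannot parse line '%s'", ln))
    }
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) {
      stop_config("config", sprintf("unknown key '%s'", key))
    }
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num
      else if (val %in% c("TRUE", "FALSE")) as.logical(val)
      else val
  }
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' @param config run configuration: a list (see [default_run_config()]),
#'   a path to a key-value config file, or `NULL` for defaults. Partial
#'   lists are completed with the defaults.
#' @param bundle optionally, an in-memory `claims_bundle` to analyze
#'   (overrides `bundle_dir`/simulation).
#' @param verbose print stage progress to stderr.
#' @return a `pipeline_report` list: `cohort`, `attrition`, `pruning_log`,
#'   `outcomes`, `channels`, `km`, `hr_table` (pooled across imputations),
#'   `reportable`, `c_index`, `c_index_ci`, `n`, `n_events`,
#'   `prevalence_pct`, `config`.
#' @export
run_pipeline <- function(config = NULL, bundle = NULL, verbose = FALSE) {
  if (is.character(config)) config <- parse_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config %||% list())
  say <- function(...) if (verbose) message(sprintf(...))

  codesets <- run_stage("codesets", {
    if (!is.null(cfg$codesets_path)) read_codesets(cfg$codesets_path)
    else check_codesets(default_codesets())
  })

  bundle <- run_stage("bundle", {
    if (!is.null(bundle)) bundle
    else if (!is.null(cfg$bundle_dir)) read_bundle(cfg$bundle_dir)
    else simulate_cohort(sim_config(n_patients = cfg$n_patients,
                                    seed = cfg$seed))
  })
  say("bundle ready: %d patients", nrow(bundle$patients))

  cb <- run_stage("cohort", build_cohort(
    bundle, codesets, gap_days = cfg$gap_days,
    min_duration_days = cfg$min_duration_days,
    washout_days = cfg$washout_days, study_start = cfg$study_start,
    study_end = cfg$study_end,
    cancer_distinct_days = cfg$cancer_distinct_days))
  cohort <- cb$cohort
  say("cohort: %d patients", nrow(cohort))
  if (nrow(cohort) == 0L) {
    stop("stage 'cohort': no patients satisfy the inclusion criteria",
         call. = FALSE)
  }

  covs <- run_stage("covariates", build_covariate_table(
    cohort, bundle, codesets, window_days = cfg$window_days,
    gap_days = cfg$gap_days))

  pruned <- run_stage("pruning", prune_covariates(
    covs, min_prevalence = cfg$min_prevalence,
    drop_labs_missing_ge = cfg$drop_labs_missing_ge))

  outcomes <- run_stage("outcomes", ascertain_outcomes_all(
    cohort, bundle, codesets, gap_days = cfg$gap_days))
  channels <- tabulate_channels(outcomes)
  say("events: %d / %d", sum(outcomes$event), nrow(outcomes))

  design <- merge(pruned$table,
                  outcomes[, .(patient_id, time = time_days, event)],
                  by = "patient_id")

  imp_spec <- imputation_spec(
    m_imputations = cfg$m_imputations, k_donors = cfg$k_donors,
    seed = make_seed(cfg$seed, 17L), max_iter = cfg$max_iter)
  completed <- run_stage("imputation", impute_pmm(design, imp_spec))

  fits <- run_stage("cox", lapply(completed, fit_cox))
  hr_table <- pool_cox_results(fits)
  c_index <- attr(hr_table, "c_index")
  ci <- run_stage("c_index", concordance_index(
    design$time, design$event, fits[[1]]$fit$linear.predictors,
    n_boot = cfg$n_boot, seed = make_seed(cfg$seed, 19L)))

  km <- run_stage("km", km_estimate(outcomes$time_days, outcomes$event))
  reportable <- filter_reportable(hr_table,
                                  band = c(cfg$band_low, cfg$band_high),
                                  alpha = cfg$alpha)

  report <- structure(list(
    cohort = cohort, attrition = cb$attrition, pruning_log = pruned$log,
    outcomes = outcomes, channels = channels, km = km,
    hr_table = hr_table, reportable = reportable,
    c_index = c_index, c_index_ci = ci$ci %||% c(NA_real_, NA_real_),
    n = nrow(cohort), n_events = sum(outcomes$event),
    prevalence_pct = pct_of(sum(outcomes$event), nrow(outcomes)),
    config = cfg
  ), class = "pipeline_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  cohort n = %d, events = %d (prevalence %.2f%%)\n",
              x$n, x$n_events, x$prevalence_pct))
  cat(sprintf("  C-index = %.3f", x$c_index))
  if (!anyNA(x$c_index_ci)) {
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$c_index_ci[1], x$c_index_ci[2]))
  }
  cat(sprintf("\n  reportable covariates: %d of %d\n",
              nrow(x$reportable), nrow(x$hr_table)))
  invisible(x)
}

#' Write pipeline artifacts as delimited text tables
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(report$attrition, file.path(dir, "attrition.csv"))
  data.table::fwrite(report$pruning_log, file.path(dir, "pruning_log.csv"))
  data.table::fwrite(report$outcomes, file.path(dir, "outcomes.csv"), na = "")
  data.table::fwrite(report$channels$any_channel,
                     file.path(dir, "channel_summary.csv"))
  hr <- data.table::copy(report$hr_table)
  hr[, reportable := name %in% report$reportable$name]
  data.table::fwrite(hr, file.path(dir, "hr_table.csv"))
  km <- data.table::data.table(time = report$km$event_times,
                               survival = report$km$survival,
                               at_risk = report$km$at_risk,
                               n_events = report$km$n_events)
  data.table::fwrite(km, file.path(dir, "km_curve.csv"))
  writeLines(c(
    sprintf("seed\t%d", report$config$seed),
    sprintf("n_cohort\t%d", report$n),
    sprintf("n_events\t%d", report$n_events),
    sprintf("prevalence_pct\t%.2f", report$prevalence_pct),
    sprintf("c_index\t%.4f", report$c_index)),
    file.path(dir, "run_manifest.txt"))
  invisible(dir)
}
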