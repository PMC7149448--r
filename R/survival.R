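# Survival analysis: Kaplan-Meier summary, adjusted Cox proportional-hazards
# model with Efron tie handling, Harrell's C, the effect-size/CI reporting
# filter, and cohort summary tables. The partial-likelihood solver is
# delegated to the survival package; all inputs and outputs are governed by
# the contracts below and checked against hand oracles in the tests.

#' Kaplan-Meier product-limit estimate
#'
#' @param times event/censoring times (days, >= 1).
#' @param events event indicators (0/1 or logical).
#' @return a `km_curve` list: `event_times` (distinct event times,
#'   ascending), `survival` (product-limit estimate after each), `at_risk`,
#'   `n_events`, and the input size `n`.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty input to km_estimate", call. = FALSE)
  stopifnot(length(times) == length(events), all(times >= 1))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep],
                 survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep],
                 n_events = fit$n.event[keep],
                 n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d distinct event times\n",
              x$n, length(x$event_times)))
  if (length(x$event_times)) {
    show <- utils::head(data.frame(time = x$event_times,
                                   at_risk = x$at_risk,
                                   events = x$n_events,
                                   survival = round(x$survival, 4)), 10L)
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' Fit the adjusted Cox proportional-hazards model
#'
#' Maximum partial likelihood with Efron tie handling; Wald confidence
#' intervals on the log scale, exponentiated; Harrell's concordance on the
#' fitted linear predictor.
#'
#' @param design data.frame/data.table containing `time`, `event`, and the
#'   covariate columns (no missing values).
#' @param covariate_cols covariates to adjust for (default: every column
#'   except `patient_id`, `time`, `event`).
#' @param conf_level Wald CI level (default 0.95).
#' @return a `cox_result` list: `table` (`data.table` of `name`, `coef`,
#'   `se`, `hr`, `ci_low`, `ci_high`, `p`), `c_index`, `n`, `n_events`,
#'   plus the raw `fit` for downstream pooling.
#' @export
fit_cox <- function(design, covariate_cols = NULL, conf_level = 0.95) {
  dd <- data.table::as.data.table(design)
  covariate_cols <- covariate_cols %||%
    setdiff(names(dd), c("patient_id", "time", "event"))
  stopifnot(all(c("time", "event") %in% names(dd)))
  if (sum(dd$event) < 2L) stop("fewer than 2 events", call. = FALSE)
  if (anyNA(dd[, ..covariate_cols])) {
    stop("design matrix has missing covariate values (impute first)",
         call. = FALSE)
  }
  # drop constant columns (inestimable) rather than failing
  keep <- covariate_cols[vapply(covariate_cols,
                                function(cc) stats::var(dd[[cc]]) > 0, TRUE)]
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", keep), collapse = " + ")))
  fit <- survival::coxph(fml, data = dd, ties = "efron", x = FALSE, y = TRUE)
  if (!is.null(fit$fail)) {
    stop(sprintf("Cox model failed to converge: %s", fit$fail), call. = FALSE)
  }
  beta <- stats::coef(fit)
  if (any(abs(beta) > 10, na.rm = TRUE)) {
    warning(sprintf("possible separation: |beta| > 10 for %s",
                    paste(names(beta)[which(abs(beta) > 10)],
                          collapse = ", ")))
  }
  if (anyNA(beta)) {
    # singular (collinear) columns: inestimable, dropped from the table
    ok <- !is.na(beta)
    beta <- beta[ok]
    fit$var <- fit$var[ok, ok, drop = FALSE]
  }
  se <- sqrt(diag(fit$var))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.table::data.table(
    name = gsub("`", "", names(beta)), coef = unname(beta), se = se,
    hr = exp(unname(beta)), ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p = 2 * stats::pnorm(-abs(beta / se)))
  structure(list(table = tab, c_index = unname(fit$concordance["concordance"]),
                 n = nrow(dd), n_events = sum(dd$event), fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> n = %d, events = %d, C-index = %.3f\n",
              x$n, x$n_events, x$c_index))
  tb <- data.table::copy(x$table)
  tb[, c("hr", "ci_low", "ci_high") :=
       lapply(.SD, round, 3L), .SDcols = c("hr", "ci_low", "ci_high")]
  print(utils::head(tb[, .(name, hr, ci_low, ci_high, p = signif(p, 3))],
                    15L), row.names = FALSE)
  invisible(x)
}

#' Harrell's concordance index with an optional bootstrap CI
#'
#' @param time,event survival outcome vectors.
#' @param lp linear predictor (higher = higher risk).
#' @param n_boot bootstrap resamples for the CI (0 disables; default 0).
#' @param seed seed for the bootstrap.
#' @return list with `c_index` and (if bootstrapped) `ci` (2.5/97.5
#'   percentiles).
#' @export
concordance_index <- function(time, event, lp, n_boot = 0L, seed = 1L) {
  dd <- data.frame(time = time, event = event, lp = lp)
  cfit <- survival::concordance(survival::Surv(time, event) ~ lp,
                                data = dd, reverse = TRUE)
  out <- list(c_index = unname(cfit$concordance))
  if (n_boot > 0L) {
    set.seed(seed)
    cs <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(dd), replace = TRUE)
      unname(survival::concordance(
        survival::Surv(time, event) ~ lp, data = dd[idx, ],
        reverse = TRUE)$concordance)
    }, numeric(1))
    out$ci <- unname(stats::quantile(cs, c(0.025, 0.975)))
  }
  out
}

#' Filter Cox results to the reportable set
#'
#' Keeps rows whose effect is both statistically significant and outside
#' the indifference band: `p <= alpha`, hazard ratio strictly outside
#' `[band[1], band[2]]`, and a confidence interval that does not cross 1.
#' Idempotent.
#'
#' @param results a `cox_result`, or its `table` (needs `hr`, `ci_low`,
#'   `ci_high`, `p`).
#' @param band indifference band for the hazard ratio (default `c(0.9,
#'   1.1)`, endpoints excluded).
#' @param alpha significance level (default 0.05).
#' @return the reportable rows, same columns as the input table.
#' @export
filter_reportable <- function(results, band = c(0.9, 1.1), alpha = 0.05) {
  tb <- if (inherits(results, "cox_result")) results$table else results
  tb <- data.table::as.data.table(tb)
  tb[p <= alpha & (hr < band[1] | hr > band[2]) &
       (ci_low > 1 | ci_high < 1)]
}

#' Summarize cohort demographics and clinical characteristics
#'
#' Counts and percentages (half-up, two decimals) for categorical and
#' binary variables, mean (SD) for age, and median (IQR) for the era
#' duration.
#'
#' @param cohort cohort table; binary 0/1 columns and `sex`/`race` are
#'   summarized if present, as are `age_at_index` and `era_len`.
#' @return list with `categorical` (`data.table`: `variable`, `level`,
#'   `n`, `pct`) and `continuous` (`data.table`: `variable`, `stat`,
#'   `value`).
#' @export
summarize_cohort <- function(cohort) {
  co <- data.table::as.data.table(cohort)
  if (nrow(co) == 0L) stop("empty cohort", call. = FALSE)
  n <- nrow(co)
  cat_rows <- list()
  for (cc in intersect(c("sex", "race"), names(co))) {
    tab <- co[, .N, by = cc]
    data.table::setorder(tab, -N)
    cat_rows[[cc]] <- data.table::data.table(
      variable = cc, level = as.character(tab[[cc]]), n = tab$N,
      pct = pct_of(tab$N, n))
  }
  bin_cols <- setdiff(names(co)[vapply(co, function(v)
    is.numeric(v) && !anyNA(v) && all(v %in% c(0, 1)), TRUE)],
    c("patient_id", "event"))
  for (cc in bin_cols) {
    k <- sum(co[[cc]])
    cat_rows[[cc]] <- data.table::data.table(
      variable = cc, level = "yes", n = k, pct = pct_of(k, n))
  }
  cont <- list()
  if ("age_at_index" %in% names(co)) {
    cont[[1]] <- data.table::data.table(
      variable = "age_at_index", stat = c("mean", "sd"),
      value = c(mean(co$age_at_index), stats::sd(co$age_at_index)))
  }
  if ("era_len" %in% names(co)) {
    q <- stats::quantile(co$era_len, c(0.25, 0.5, 0.75), type = 2)
    cont[[2]] <- data.table::data.table(
      variable = "era_len", stat = c("q1", "median", "q3", "max"),
      value = c(q[[1]], q[[2]], q[[3]], max(co$era_len)))
  }
  list(categorical = data.table::rbindlist(cat_rows),
       continuous = data.table::rbindlist(cont), n = n)
}

#' Pool Cox fits across imputations into a hazard-ratio table
#'
#' Applies [pool_estimates()] to the log-hazard coefficients of M
#' [fit_cox()] results and returns the exponentiated pooled table.
#'
#' @param fits list of `cox_result` objects fit to M completed datasets.
#' @param conf_level CI level (default 0.95).
#' @return `data.table`: `name`, `hr`, `ci_low`, `ci_high`, `p`, `se_log`
#'   (pooled SE on the log scale), `c_index` attribute = mean C across
#'   imputations.
#' @export
pool_cox_results <- function(fits, conf_level = 0.95) {
  per <- lapply(fits, function(f) {
    list(coef = stats::setNames(f$table$coef, f$table$name),
         var = stats::setNames(f$table$se^2, f$table$name))
  })
  pooled <- pool_estimates(per, conf_level)
  out <- pooled[, .(name, hr = exp(estimate), ci_low = exp(ci_low),
                    ci_high = exp(ci_high), p, se_log = se)]
  data.table::setattr(out, "c_index",
                      mean(vapply(fits, `[[`, numeric(1), "c_index")))
  out[]
}
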