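# Multiple imputation of missing laboratory averages by predictive mean
# matching (PMM, type-1), with chained equations across incomplete columns
# and Rubin's rules (Barnard-Rubin degrees of freedom) for pooling.
#
# For each incomplete column y with predictors X:
#   1. least squares on the observed rows: beta_hat, sigma_hat;
#   2. Bayesian parameter draw: sigma*^2 ~ SSR / chi^2_df, then
#      beta* ~ N(beta_hat, sigma*^2 (X'X)^-1);
#   3. match each missing row's prediction X_mis beta* to the k observed
#      rows with closest X_obs beta_hat, draw one donor uniformly, and
#      impute that donor's *observed* value.
# Every imputed value is therefore an observed value of the same column
# (support preservation).

#' Imputation specification
#'
#' @param m_imputations number of completed datasets M (>= 2, default 5).
#' @param k_donors donor pool size for matching (>= 1, default 5).
#' @param predictor_names columns used as regressors (complete by
#'   construction); incomplete lab columns additionally predict each other
#'   through the chained-equations loop.
#' @param seed integer seed.
#' @param max_iter chained-equation sweeps per imputation (default 10).
#' @return an `imputation_spec` list.
#' @export
imputation_spec <- function(m_imputations = 5L, k_donors = 5L,
                            predictor_names = NULL, seed = 1L,
                            max_iter = 10L) {
  if (m_imputations < 2L) stop_config("m_imputations", "must be >= 2")
  if (k_donors < 1L) stop_config("k_donors", "must be >= 1")
  structure(list(m_imputations = as.integer(m_imputations),
                 k_donors = as.integer(k_donors),
                 predictor_names = predictor_names,
                 seed = as.integer(seed), max_iter = as.integer(max_iter)),
            class = "imputation_spec")
}

#' Multiply impute missing lab columns by predictive mean matching
#'
#' @param table data.frame/data.table; columns with any `NA` among
#'   `target_cols` are imputed. All predictor columns must be complete.
#' @param spec an [imputation_spec()].
#' @param target_cols columns eligible for imputation (default: all
#'   `lab_*` columns).
#' @return list of M completed `data.table`s.
#' @export
impute_pmm <- function(table, spec = imputation_spec(),
                       target_cols = NULL) {
  tb <- data.table::as.data.table(table)
  if (is.null(target_cols)) {
    target_cols <- grep("^lab_", names(tb), value = TRUE)
  }
  targets <- target_cols[vapply(target_cols,
                                function(cc) anyNA(tb[[cc]]), TRUE)]
  # survival outcome columns are excluded from the default predictor set
  preds <- spec$predictor_names %||%
    setdiff(names(tb), c("patient_id", target_cols,
                         "event", "time", "time_days"))
  for (cc in targets) {
    if (!is.numeric(tb[[cc]])) {
      stop(sprintf("type error: target column '%s' is not numeric", cc),
           call. = FALSE)
    }
    if (sum(!is.na(tb[[cc]])) < spec$k_donors) {
      stop(sprintf("fewer than %d complete cases in column '%s'",
                   spec$k_donors, cc), call. = FALSE)
    }
  }
  for (cc in preds) {
    if (anyNA(tb[[cc]])) {
      stop(sprintf("predictor column '%s' has missing values", cc),
           call. = FALSE)
    }
  }
  if (!length(targets)) {
    return(lapply(seq_len(spec$m_imputations),
                  function(i) data.table::copy(tb)))
  }
  miss_idx <- lapply(targets, function(cc) which(is.na(tb[[cc]])))
  names(miss_idx) <- targets

  lapply(seq_len(spec$m_imputations), function(m) {
    set.seed(make_seed(spec$seed, m))
    dat <- data.table::copy(tb)
    # initialize missing entries by random draws from the observed values
    for (cc in targets) {
      obs <- dat[[cc]][!is.na(dat[[cc]])]
      data.table::set(dat, miss_idx[[cc]], cc,
                      sample(obs, length(miss_idx[[cc]]), replace = TRUE))
    }
    for (iter in seq_len(spec$max_iter)) {
      for (cc in targets) {
        mis <- miss_idx[[cc]]
        other <- setdiff(targets, cc)
        Xcols <- c(preds, other)
        X <- cbind(1, as.matrix(dat[, ..Xcols]))
        y_true <- tb[[cc]]          # observed values only; NA where missing
        obs <- which(!is.na(y_true))
        donors <- pmm_match(X[obs, , drop = FALSE], y_true[obs],
                            X[mis, , drop = FALSE], spec$k_donors)
        data.table::set(dat, mis, cc, donors)
      }
    }
    dat
  })
}

# One PMM draw: Bayesian regression draw on the observed rows, then
# k-nearest-donor matching on predicted means. Returns imputed values for
# the missing rows.
pmm_match <- function(X_obs, y_obs, X_mis, k) {
  if (nrow(X_mis) == 0L) return(numeric())
  qr_x <- qr(X_obs)
  beta_hat <- qr.coef(qr_x, y_obs)
  beta_hat[is.na(beta_hat)] <- 0      # rank-deficient columns drop out
  res <- y_obs - as.numeric(X_obs %*% beta_hat)
  df <- max(nrow(X_obs) - qr_x$rank, 1L)
  sigma2_star <- sum(res^2) / stats::rchisq(1L, df)
  R <- qr.R(qr_x)
  keep <- qr_x$pivot[seq_len(qr_x$rank)]
  Rinv <- backsolve(R[seq_len(qr_x$rank), seq_len(qr_x$rank), drop = FALSE],
                    diag(qr_x$rank))
  beta_star <- beta_hat
  beta_star[keep] <- beta_hat[keep] +
    sqrt(sigma2_star) * as.numeric(Rinv %*% stats::rnorm(qr_x$rank))
  yhat_obs <- as.numeric(X_obs %*% beta_hat)
  yhat_mis <- as.numeric(X_mis %*% beta_star)
  # k nearest donors by |yhat_obs - yhat_mis|, one drawn uniformly
  ord <- order(yhat_obs)
  y_sorted <- y_obs[ord]
  p_sorted <- yhat_obs[ord]
  n_obs <- length(p_sorted)
  pos <- findInterval(yhat_mis, p_sorted)
  # candidate window of 2k sorted neighbours around the insertion point
  offs <- seq(-k + 1L, k)
  cand <- outer(pos, offs, `+`)
  cand[cand < 1L] <- 1L
  cand[cand > n_obs] <- n_obs
  dist <- abs(matrix(p_sorted[cand], nrow(cand)) - yhat_mis)
  # uniform draw among each row's k closest candidates
  ranks <- t(apply(dist, 1L, order))[, seq_len(min(k, ncol(cand))),
                                     drop = FALSE]
  choice <- ranks[cbind(seq_len(nrow(ranks)),
                        sample.int(ncol(ranks), nrow(ranks),
                                   replace = TRUE))]
  y_sorted[cand[cbind(seq_len(nrow(cand)), choice)]]
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' @param per_imputation_fits list of M fits, each a list with `coef`
#'   (named numeric) and `var` (variance-covariance matrix or vector of
#'   squared SEs, same names).
#' @param conf_level confidence level for pooled intervals (default 0.95).
#' @return `data.table` with per-coefficient `name`, `estimate` (pooled
#'   mean), `se` (total variance, Rubin), `ci_low`, `ci_high`, `p`, `df`
#'   (Barnard-Rubin).
#' @export
pool_estimates <- function(per_imputation_fits, conf_level = 0.95) {
  M <- length(per_imputation_fits)
  if (M < 2L) stop("pooling requires M >= 2 fits", call. = FALSE)
  nms <- names(per_imputation_fits[[1]]$coef)
  for (f in per_imputation_fits) {
    if (!identical(names(f$coef), nms)) {
      stop("alignment error: coefficient names differ across fits",
           call. = FALSE)
    }
  }
  co <- do.call(rbind, lapply(per_imputation_fits, function(f) f$coef))
  vars <- do.call(rbind, lapply(per_imputation_fits, function(f) {
    v <- f$var
    if (is.matrix(v)) diag(v) else v
  }))
  qbar <- colMeans(co)
  ubar <- colMeans(vars)                       # within-imputation variance
  b <- apply(co, 2L, stats::var)               # between-imputation variance
  t_var <- ubar + (1 + 1 / M) * b
  # Barnard-Rubin adjusted degrees of freedom (large-sample complete-data df)
  r <- ifelse(ubar > 0, (1 + 1 / M) * b / ubar, Inf)
  df_old <- (M - 1) * (1 + 1 / r)^2            # r = Inf -> M - 1
  df_old[b == 0] <- Inf
  lambda <- ifelse(t_var > 0, (1 + 1 / M) * b / t_var, 0)
  df_obs <- 1e6 * (1 - lambda) * (1e6 + 1) / (1e6 + 3)
  df <- ifelse(is.infinite(df_old), df_obs,
               df_old * df_obs / (df_old + df_obs))
  se <- sqrt(t_var)
  # degenerate columns (zero total or zero adjusted df) get NA inference
  usable <- se > 0 & df > 0
  p <- a <- rep(NA_real_, length(se))
  p[usable] <- 2 * stats::pt(-abs(qbar[usable] / se[usable]), df[usable])
  a[usable] <- stats::qt(1 - (1 - conf_level) / 2, df[usable])
  ci_low <- ifelse(se == 0, qbar, qbar - a * se)
  ci_high <- ifelse(se == 0, qbar, qbar + a * se)
  data.table::data.table(name = nms, estimate = qbar, se = se,
                         ci_low = ci_low, ci_high = ci_high, p = p, df = df)
}
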