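# Small shared helpers: day arithmetic, rounding, seeds, input checks.

#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero on the positive
#' axis (2.345 -> 2.35 at 2 digits), matching how the source tables print
#' percentages. Base `round()` uses banker's rounding and cannot be used for
#' table reproduction.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count, rounded half-up to two decimals
#'
#' @param n count (numerator).
#' @param total denominator.
#' @param digits decimal places (default 2).
#' @return numeric percentage on the 0-100 scale.
#' @export
pct_of <- function(n, total, digits = 2) {
  stopifnot(total > 0)
  round_half_up(100 * n / total, digits)
}

# Derive a per-stage seed from a root seed. Keeps results < 2^31 for any
# root seed the CLI accepts (|seed| < 2^20 is plenty; larger seeds are folded).
make_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  (abs(as.integer(seed)) %% 1048576L) * 1024L + as.integer(stage) %% 1024L
}

# Integer day offsets <-> calendar dates. All internal arithmetic is in day
# offsets from `epoch`; ISO-8601 only appears in readers/writers.
day_to_date <- function(day, epoch = "2006-01-01") {
  as.Date(epoch) + as.integer(day)
}

date_to_day <- function(date, epoch = "2006-01-01") {
  as.integer(as.Date(date) - as.Date(epoch))
}

# Completed years between two day offsets (birth -> index).
completed_years <- function(birth_day, at_day) {
  as.integer(floor((at_day - birth_day) / 365.25))
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, lo = 0, hi = 1) {
  if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi)) {
    stop_config(field, sprintf("must be numeric in [%g, %g]", lo, hi))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
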