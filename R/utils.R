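# Internal helpers shared across modules.

#' Parameters of a mean-1 lognormal with a given coefficient of variation
#'
#' @param cv coefficient of variation (fraction, >= 0).
#' @return list with `meanlog` and `sdlog`; cv = 0 gives a point mass at 1.
#' @keywords internal
#' @noRd
lognormal_mean1 <- function(cv) {
  stopifnot(is.numeric(cv), length(cv) == 1L, cv >= 0)
  sdlog <- sqrt(log1p(cv^2))
  list(meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Deterministic seed-splitting rule. Child streams are indexed by two small
# non-negative integers (here: specimen index, well index); the rule is a
# fixed affine hash modulo the largest 32-bit prime, so adding specimens or
# wells never perturbs the stream of an existing (i, j) pair. All operands
# stay below 2^53, so the double-precision modulo is exact.
child_seed <- function(master, i, j = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647
  as.integer(((master %% m) * 48271 + i * 100003 + j * 101) %% m)
}

#' Sample coefficient of variation in percent
#'
#' 100 * (n-1 sample standard deviation) / mean. Returns `NA` with no error
#' when the mean is zero or fewer than two values are supplied.
#' @keywords internal
#' @noRd
cv_percent <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}

# Least-squares slope of y on t (closed form). With exactly two points this
# is the difference quotient.
ls_slope <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 2L)
  tc <- t - mean(t)
  ss <- sum(tc^2)
  if (ss == 0) {
    abort("cannot fit a slope: all time points in the window are identical")
  }
  sum(tc * (y - mean(y))) / ss
}

# Stop unless `x` is a single finite number satisfying `ok`.
check_scalar <- function(x, name, ok = function(v) TRUE, what = "valid") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !ok(x)) {
    abort(sprintf("`%s` must be a single finite %s number", name, what))
  }
  invisible(x)
}
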