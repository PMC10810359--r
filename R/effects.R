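# Effect-interpretation arithmetic for log-linear count models: a
# coefficient beta_j multiplies the expected birth count by exp(beta_j)
# per unit of x_j, all else held fixed.

#' Relative rate implied by a log-scale coefficient
#'
#' @param beta_j coefficient on the log-mean scale.
#' @return `exp(beta_j)`: the multiplicative change in the expected count
#'   for a one-unit increase in the predictor.
#' @examples
#' relative_rate(-0.1021)  # urban vs rural: 0.903
#' @export
relative_rate <- function(beta_j) {
  stopifnot(is.finite(beta_j))
  exp(beta_j)
}

#' Rate ratio between two dummy levels
#'
#' @param beta_a,beta_b coefficients of the two dummies (same base
#'   category).
#' @return `exp(beta_a - beta_b)`: expected counts at level a relative to
#'   level b.
#' @examples
#' rate_ratio(-0.102, -0.77885)  # male vs female contraception: 1.97
#' @export
rate_ratio <- function(beta_a, beta_b) {
  stopifnot(is.finite(beta_a), is.finite(beta_b))
  exp(beta_a - beta_b)
}

#' Percentage change in the expected count
#'
#' @param beta log-scale coefficient.
#' @param delta change in the predictor (e.g. 1 for one education level).
#' @return `100 * (exp(beta * delta) - 1)`.
#' @examples
#' pct_change(0.095, 1)  # ~10% more births per education level
#' @export
pct_change <- function(beta, delta) {
  stopifnot(is.finite(beta), is.finite(delta))
  100 * (exp(beta * delta) - 1)
}

#' Wald confidence interval for a coefficient
#'
#' Normal-approximation interval `beta +/- z * se`.  For the conventional
#' 95% level the multiplier is fixed at exactly 1.96 (the two-decimal
#' tabulated value); other levels use the exact normal quantile.
#'
#' @param beta point estimate.
#' @param se positive standard error.
#' @param level confidence level in (0, 1); default 0.95.
#' @return Named vector `c(lo, hi)`.
#' @examples
#' wald_ci(-0.088, 0.021)  # (-0.12916, -0.04684)
#' @export
wald_ci <- function(beta, se, level = 0.95) {
  if (!is.finite(se) || se <= 0) stop("se must be positive", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  z <- if (isTRUE(all.equal(level, 0.95))) 1.96
       else stats::qnorm(1 - (1 - level) / 2)
  c(lo = beta - z * se, hi = beta + z * se)
}

#' Exponentiate a confidence interval onto the rate-ratio scale
#'
#' @param lo,hi interval endpoints on the log scale, or a length-2 vector
#'   in `lo`.
#' @return Named vector `c(lo, hi)` of exponentiated endpoints.
#' @examples
#' exp_ci(-0.1612, -0.024)  # (0.851, 0.976)
#' @export
exp_ci <- function(lo, hi = NULL) {
  if (is.null(hi)) { hi <- lo[[2]]; lo <- lo[[1]] }
  c(lo = exp(unname(lo)), hi = exp(unname(hi)))
}

#' Conventional significance code for a p-value
#'
#' The usual R bracket rule: `***` below 0.001, `**` below 0.01, `*`
#' below 0.05, `.` below 0.1, a space otherwise.
#'
#' @param p p-value in \[0, 1\].
#' @return One of `"***"`, `"**"`, `"*"`, `"."`, `" "`.
#' @export
significance_code <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1)
    stop("p must lie in [0, 1]", call. = FALSE)
  if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else if (p < 0.1) "."
  else " "
}
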