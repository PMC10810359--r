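# Fertility measures from aggregated births (B) and woman-years of
# exposure (E) over the seven 5-year reproductive age groups.

#' Age-specific fertility rates
#'
#' `ASFR_g = 1000 * B_g / E_g`: births per 1,000 woman-years of exposure
#' in each 5-year age group.  A group with neither births nor exposure
#' gets a 0 rate and is listed in the `"empty_groups"` attribute; births
#' without exposure are an error.
#'
#' @param B length-7 vector of total births per group (may be non-integer
#'   when model-predicted).
#' @param E length-7 vector of total woman-years per group.
#' @return Length-7 numeric vector of rates per 1,000 woman-years.
#' @export
asfr <- function(B, E) {
  stopifnot(length(B) == 7L, length(E) == 7L, all(B >= 0), all(E >= 0))
  if (any(B > 0 & E == 0))
    stop("births recorded in a group with zero exposure", call. = FALSE)
  out <- ifelse(E > 0, 1000 * B / E, 0)
  names(out) <- age_group_labels()
  attr(out, "empty_groups") <- which(E == 0 & B == 0)
  out
}

#' Total fertility rate
#'
#' `TFR = 5 * sum(ASFR_g) / 1000`: the hypothetical number of births per
#' woman over the reproductive span if the current age-specific schedule
#' held with no mortality.  The division by 1,000 converts the per-1,000
#' ASFRs to a per-woman rate.
#'
#' @param asfr_vector length-7 ASFR vector (per 1,000 woman-years).
#' @return Births per woman.
#' @export
tfr <- function(asfr_vector) {
  if (length(asfr_vector) != 7L)
    stop("asfr_vector must have length 7", call. = FALSE)
  5 * sum(asfr_vector) / 1000
}

#' General fertility rate
#'
#' `GFR = 1000 * sum(B_g) / sum(E_g)`: total births per 1,000 woman-years
#' of exposure across all reproductive age groups (an exposure-weighted
#' mean of the ASFRs).
#'
#' @inheritParams asfr
#' @return Births per 1,000 woman-years.
#' @export
gfr <- function(B, E) {
  stopifnot(length(B) == 7L, length(E) == 7L)
  if (sum(E) <= 0) stop("total exposure is zero", call. = FALSE)
  1000 * sum(B) / sum(E)
}

#' Gross reproduction rate
#'
#' `GRR = 5 * sum(ASFR_g * P_g) / 1000`: like the TFR but counting only
#' daughters, with `P_g` the proportion of female births to women in age
#' group g (from an observed sex ratio, census or administrative records;
#' no mortality adjustment).
#'
#' @param asfr_vector length-7 ASFR vector (per 1,000 woman-years).
#' @param p_female female-birth proportions: a scalar or length-7 vector
#'   in \[0, 1\].
#' @return Daughters per woman.  Equals `tfr/2` when `p_female` is 0.5.
#' @export
grr <- function(asfr_vector, p_female = 0.5) {
  if (length(asfr_vector) != 7L)
    stop("asfr_vector must have length 7", call. = FALSE)
  if (any(p_female < 0 | p_female > 1))
    stop("p_female must lie in [0, 1]", call. = FALSE)
  p <- rep_len(p_female, 7L)
  5 * sum(asfr_vector * p) / 1000
}

#' All four fertility measures from group totals
#'
#' @inheritParams asfr
#' @param p_female female-birth proportion(s), see [grr()].
#' @return Object of class `fert_estimates`: list with `asfr` (per 1,000
#'   woman-years), `tfr` (births per woman), `gfr` (per 1,000
#'   woman-years), `grr` (daughters per woman) and `p_female`.
#' @export
fertility_estimates <- function(B, E, p_female = 0.5) {
  a <- asfr(B, E)
  structure(list(asfr = a, tfr = tfr(a), gfr = gfr(B, E),
                 grr = grr(a, p_female), p_female = rep_len(p_female, 7L)),
            class = "fert_estimates")
}

#' @export
print.fert_estimates <- function(x, ...) {
  cat("ASFR (births per 1,000 woman-years):\n")
  print(round(x$asfr, 2))
  cat(sprintf("TFR = %.3f births per woman\n", x$tfr))
  cat(sprintf("GFR = %.2f births per 1,000 woman-years\n", x$gfr))
  cat(sprintf("GRR = %.3f daughters per woman\n", x$grr))
  invisible(x)
}
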