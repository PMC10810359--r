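#' Century-month-code date arithmetic
#'
#' DHS surveys encode dates as the number of months elapsed since January
#' 1900 (the century month code, CMC; January 1900 = 1).  All exposure and
#' birth-allocation arithmetic in this package works at CMC (month)
#' resolution.
#'
#' @param year calendar year (>= 1900).
#' @param month calendar month, 1--12.
#' @return Integer CMC: `12 * (year - 1900) + month`.
#' @examples
#' cmc_from_date(1900, 1)  # 1
#' cmc_from_date(2017, 12) # 1416
#' @export
cmc_from_date <- function(year, month) {
  if (any(month < 1 | month > 12)) stop("month must be in 1..12", call. = FALSE)
  if (any(year < 1900)) stop("year must be >= 1900", call. = FALSE)
  as.integer(12L * (as.integer(year) - 1900L) + as.integer(month))
}

# Reproductive-age window in completed months and 5-year group width.
.AGE_MIN_MONTHS <- 180L  # 15 years
.AGE_MAX_MONTHS <- 600L  # 50 years (exclusive)
.GROUP_WIDTH <- 60L
.N_GROUPS <- 7L

#' Age-group labels for the seven 5-year reproductive age groups
#'
#' @return Character vector `"15-19"` ... `"45-49"`, indexed by group
#'   `g = 0..6`.
#' @export
age_group_labels <- function() {
  lo <- seq(15L, 45L, by = 5L)
  sprintf("%d-%d", lo, lo + 4L)
}

# Completed age in months during calendar month t for a woman born in month
# dob: she has lived t - dob - 1 full months at the start of month t.  A
# woman whose interview-month age (interview - dob) is exactly 240 months
# therefore spends her whole preceding 36-month window below age 20.
.age_in_month <- function(t, dob_cmc) t - dob_cmc - 1L

.group_of_age <- function(age_months) {
  g <- (age_months - .AGE_MIN_MONTHS) %/% .GROUP_WIDTH
  g[age_months < .AGE_MIN_MONTHS | age_months >= .AGE_MAX_MONTHS] <- NA_integer_
  as.integer(g)
}

#' Person-months of exposure by 5-year age group
#'
#' Splits a reference window of `window_months` months ending at the
#' interview (the half-open interval `(interview - w, interview]`, so the
#' interview month counts) across the mother's 5-year age groups.  Months
#' spent below age 15 or at age 50 and above are excluded.  For windows of
#' up to 60 months a woman contributes to at most two adjacent groups.
#'
#' @param dob_cmc woman's date of birth in CMC.
#' @param interview_cmc interview date in CMC (`> dob_cmc`).
#' @param window_months positive window length in months (12, 36 or 60 for
#'   the standard DHS responses).
#' @return A data.frame with columns `g` (group index 0..6) and `months`
#'   (positive exposure in months); zero rows if the woman is outside
#'   ages \[15, 50) for the whole window.
#' @examples
#' woman_exposure(0, 258, 36)  # 18 months in 15-19, 18 in 20-24
#' @export
woman_exposure <- function(dob_cmc, interview_cmc, window_months) {
  if (window_months <= 0) stop("window_months must be positive", call. = FALSE)
  if (interview_cmc <= dob_cmc)
    stop("interview_cmc must exceed dob_cmc", call. = FALSE)
  w <- as.integer(window_months)
  dob_cmc <- as.integer(dob_cmc)
  interview_cmc <- as.integer(interview_cmc)
  # Completed ages over window months t = interview-w+1 .. interview.
  a_lo <- interview_cmc - w - dob_cmc
  a_hi <- interview_cmc - dob_cmc - 1L
  a_lo <- max(a_lo, .AGE_MIN_MONTHS)
  a_hi <- min(a_hi, .AGE_MAX_MONTHS - 1L)
  if (a_lo > a_hi)
    return(data.frame(g = integer(0), months = integer(0)))
  g_lo <- .group_of_age(a_lo)
  g_hi <- .group_of_age(a_hi)
  gs <- seq.int(g_lo, g_hi)
  months <- vapply(gs, function(g) {
    lo <- max(a_lo, .AGE_MIN_MONTHS + g * .GROUP_WIDTH)
    hi <- min(a_hi, .AGE_MIN_MONTHS + (g + 1L) * .GROUP_WIDTH - 1L)
    hi - lo + 1L
  }, integer(1))
  data.frame(g = as.integer(gs), months = as.integer(months))
}

#' Allocate dated births to the mother's 5-year age groups
#'
#' Births with CMC inside the window `(interview - w, interview]` are
#' assigned to the age group the mother occupies in the birth month (the
#' same month-age convention as [woman_exposure()], so a counted birth
#' always falls in a group the mother has positive exposure in).  Births at
#' mother ages outside \[15, 50) are dropped; their count is returned in the
#' `"dropped"` attribute.
#'
#' @param birth_cmcs integer vector of birth dates in CMC (possibly empty).
#' @param dob_cmc,interview_cmc,window_months as in [woman_exposure()].
#' @return Integer vector of length 7 (births per group `g = 0..6`) with
#'   attribute `dropped`.
#' @export
allocate_births <- function(birth_cmcs, dob_cmc, interview_cmc, window_months) {
  if (length(birth_cmcs) && any(birth_cmcs <= dob_cmc))
    stop("birth_cmc must exceed the mother's dob_cmc", call. = FALSE)
  counts <- integer(.N_GROUPS)
  dropped <- 0L
  if (length(birth_cmcs)) {
    in_win <- birth_cmcs > interview_cmc - window_months &
      birth_cmcs <= interview_cmc
    b <- birth_cmcs[in_win]
    g <- .group_of_age(.age_in_month(b, dob_cmc))
    dropped <- sum(is.na(g))
    tab <- table(factor(g[!is.na(g)], levels = 0:(.N_GROUPS - 1L)))
    counts <- as.integer(tab)
  }
  structure(counts, dropped = dropped)
}

#' Build the person-year table from a population
#'
#' Converts woman-level birth-history records into the long-format
#' person-year data that the count regressions are fitted on: one row per
#' (woman, contributed age group), carrying years of exposure (the model
#' offset), the births the woman had while in that group inside the window,
#' and a copy of the woman's design-matrix row.  A woman whose window spans
#' a 5-year-group boundary is tallied twice, once per group.
#'
#' @param women a `fert_population` (see [generate_population()]) or a
#'   data.frame of woman records with `woman_id`, `dob_cmc`,
#'   `interview_cmc` columns.
#' @param births data.frame with columns `woman_id`, `birth_cmc`; taken
#'   from the population object when `women` is a `fert_population`.
#' @param window_months reference window length in months; defaults to the
#'   population's configured window.
#' @param covariates optional numeric matrix of per-woman covariate rows
#'   (same order as `women`); defaults to [build_design_matrix()] applied to
#'   the records.
#' @return A data.frame with columns `woman_id`, `g`, `exposure_years`,
#'   `births`, then one column per design-matrix covariate.  The number of
#'   dropped out-of-age births is in the `"dropped_births"` attribute.
#' @export
build_person_year_table <- function(women, births = NULL, window_months = NULL,
                                    covariates = NULL) {
  if (inherits(women, "fert_population")) {
    if (is.null(births)) births <- women$births
    if (is.null(window_months)) window_months <- women$config$window_months
    women <- women$women
  }
  if (is.null(window_months)) stop("window_months is required", call. = FALSE)
  if (is.null(births))
    births <- data.frame(woman_id = integer(0), birth_cmc = integer(0))
  if (is.null(covariates)) covariates <- build_design_matrix(women)
  stopifnot(nrow(covariates) == nrow(women))

  bk <- split(births$birth_cmc, factor(births$woman_id,
                                       levels = women$woman_id))
  n_dropped <- 0L
  rows <- vector("list", nrow(women))
  for (i in seq_len(nrow(women))) {
    exp_i <- woman_exposure(women$dob_cmc[i], women$interview_cmc[i],
                            window_months)
    if (nrow(exp_i) == 0L) next
    b_i <- allocate_births(bk[[i]], women$dob_cmc[i], women$interview_cmc[i],
                           window_months)
    n_dropped <- n_dropped + attr(b_i, "dropped")
    rows[[i]] <- data.frame(
      woman_id = women$woman_id[i],
      g = exp_i$g,
      exposure_years = exp_i$months / 12,
      births = as.integer(b_i[exp_i$g + 1L]),
      row = i
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- cbind(
      data.frame(woman_id = integer(0), g = integer(0),
                 exposure_years = numeric(0), births = integer(0)),
      as.data.frame(covariates[0, , drop = FALSE])
    )
    attr(out, "dropped_births") <- 0L
    return(out)
  }
  long <- do.call(rbind, rows)
  out <- cbind(long[c("woman_id", "g", "exposure_years", "births")],
               as.data.frame(covariates[long$row, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "dropped_births") <- n_dropped
  out
}

#' Aggregate a person-year table to group totals
#'
#' Sums births and woman-years of exposure over the seven 5-year age
#' groups; these totals are the numerator and denominator vectors of the
#' age-specific fertility rates.
#'
#' @param table a person-year table from [build_person_year_table()], or
#'   any data.frame with columns `g`, `births`, `exposure_years`.
#' @return An object of class `exposure_table`: a list with integer vector
#'   `B` and numeric vector `E`, both of length 7.
#' @export
aggregate_exposure <- function(table) {
  if (nrow(table) == 0L)
    return(structure(list(B = integer(.N_GROUPS), E = numeric(.N_GROUPS)),
                     class = "exposure_table"))
  f <- factor(table$g, levels = 0:(.N_GROUPS - 1L))
  B <- as.integer(tapply(table$births, f, sum, default = 0L))
  E <- as.numeric(tapply(table$exposure_years, f, sum, default = 0))
  structure(list(B = B, E = E), class = "exposure_table")
}

#' @export
print.exposure_table <- function(x, ...) {
  cat("Births and woman-years of exposure by age group\n")
  m <- rbind(births = x$B, exposure = round(x$E, 2))
  colnames(m) <- age_group_labels()
  print(m)
  invisible(x)
}
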