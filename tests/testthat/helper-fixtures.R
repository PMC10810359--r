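# Shared fixtures, built in code at test time.

# Small woman-records frame with only the fields the exposure module needs;
# covariates supplied as an explicit intercept column.
exposure_women <- function(dob, interview) {
  data.frame(woman_id = seq_along(dob), dob_cmc = dob,
             interview_cmc = interview)
}

intercept_only <- function(n) matrix(1, n, 1, dimnames = list(NULL, "Intercept"))

# Independent month-by-month tally of exposure by age group: the brute-force
# oracle the closed-form interval intersection is validated against.
month_loop_exposure <- function(dob_cmc, interview_cmc, window_months) {
  out <- integer(7)
  for (t in (interview_cmc - window_months + 1L):interview_cmc) {
    a <- t - dob_cmc - 1L
    if (a >= 180L && a < 600L) {
      g <- (a - 180L) %/% 60L
      out[g + 1L] <- out[g + 1L] + 1L
    }
  }
  out
}

# Small 3-column design with one continuous and one binary covariate.
small_design <- function(n, seed = 1) {
  fertcount:::with_seed(seed, cbind(Intercept = 1,
                                    x1 = stats::rnorm(n),
                                    x2 = stats::rbinom(n, 1, 0.4)))
}

# Simulate from each family at the row level (design + offset known).
simulate_counts <- function(family, X, beta, offset = NULL, gamma = NULL,
                            r = NULL, seed = 1) {
  n <- nrow(X)
  if (is.null(offset)) offset <- numeric(n)
  mu <- exp(offset + drop(X %*% beta))
  fertcount:::with_seed(seed, {
    y <- switch(family,
                poisson = stats::rpois(n, mu),
                negbin = stats::rnbinom(n, size = r, mu = mu),
                zip = stats::rpois(n, mu),
                zinb = stats::rnbinom(n, size = r, mu = mu))
    if (family %in% c("zip", "zinb")) {
      theta <- stats::plogis(drop(X %*% gamma))
      y[stats::runif(n) < theta] <- 0L
    }
    as.integer(y)
  })
}

# Intercept-only synthetic_config with all non-intercept coefficients zero.
flat_config <- function(n_women, family, b0, g0 = NULL, r = 2,
                        window = 36, seed = 1) {
  p <- length(design_columns())
  synthetic_config(
    n_women, family = family, window_months = window,
    count_coefs = c(b0, rep(0, p - 1L)),
    inflation_coefs = c(if (is.null(g0)) 0 else g0, rep(0, p - 1L)),
    dispersion_r = r, seed = seed)
}
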