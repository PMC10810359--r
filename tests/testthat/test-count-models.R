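test_that("negative log-likelihoods match closed forms", {
  X1 <- matrix(1, 1, 1)
  # Poisson, y = 0, mu = 1: -log e^{-1} = 1
  expect_equal(neg_log_likelihood("poisson", 0, X1, 0), 1)
  # ZIP, y = 0, mu = 1, theta = 0.2: -log(0.2 + 0.8 e^{-1})
  got <- neg_log_likelihood("zip", c(0, qlogis(0.2)), X1, 0)
  expect_equal(got, -log(0.2 + 0.8 * exp(-1)), tolerance = 1e-10)
  expect_equal(round(got, 4), 0.7046)
  # ZIP with theta ~ 0 collapses to the Poisson likelihood
  X <- small_design(50, seed = 2)
  y <- simulate_counts("poisson", X, c(0.3, 0.2, -0.1), seed = 3)
  expect_equal(neg_log_likelihood("zip", c(0.3, 0.2, -0.1, -500, 0, 0), X, y),
               neg_log_likelihood("poisson", c(0.3, 0.2, -0.1), X, y),
               tolerance = 1e-9)
  expect_error(neg_log_likelihood("poisson", c(0, 0), X1, 0), "length")
  expect_error(neg_log_likelihood("poisson", 0, X1, -1), "nonnegative")
})

test_that("ZIP pmf is a proper distribution", {
  X1 <- matrix(1, 1, 1)
  for (mu in c(0.3, 1, 4)) for (theta in c(0.05, 0.3, 0.8)) {
    pmf <- vapply(0:60, function(k)
      exp(-neg_log_likelihood("zip", c(log(mu), qlogis(theta)), X1, k)),
      numeric(1))
    expect_lt(abs(sum(pmf) - 1), 1e-10)
  }
})

test_that("ZIP moments follow the mixture pmf and Monte Carlo agrees", {
  expect_equal(unname(zip_moments(2, 0)), c(2, 2))
  expect_equal(unname(zip_moments(2, 1)), c(0, 0))
  m <- zip_moments(2, 0.5)
  expect_equal(unname(m["mean"]), 1.0)
  expect_equal(unname(m["variance"]), 2.0)
  # Monte-Carlo oracle straight from the mixture definition
  sim <- fertcount:::with_seed(5, {
    z <- stats::runif(2e5) < 0.5
    y <- stats::rpois(2e5, 2); y[z] <- 0L; y
  })
  expect_lt(abs(mean(sim) - m["mean"]), 0.02)
  expect_lt(abs(stats::var(sim) - m["variance"]), 0.05)
  expect_error(zip_moments(2, 1.5), "theta")
})

test_that("Poisson MLE matches closed forms and the IRLS oracle", {
  n <- 30
  X1 <- matrix(1, n, 1, dimnames = list(NULL, "Intercept"))
  fit <- fit_poisson(X1, rep(3L, n))
  expect_equal(unname(fit$beta), log(3), tolerance = 1e-9)
  # with offset the intercept is the log occurrence rate
  E <- fertcount:::with_seed(1, stats::runif(n, 0.5, 4))
  y <- rep(2L, n)
  fit <- fit_poisson(X1, y, offset = log(E))
  expect_equal(unname(fit$beta), log(sum(y) / sum(E)), tolerance = 1e-9)
  # 20-row fixture: independent oracle is stats::glm
  X <- small_design(20, seed = 6)
  yy <- simulate_counts("poisson", X, c(0.5, 0.3, -0.2), seed = 7)
  off <- log(fertcount:::with_seed(8, stats::runif(20, 0.5, 2)))
  fit <- fit_poisson(X, yy, off)
  oracle <- stats::glm(yy ~ x1 + x2, family = stats::poisson(),
                       data = as.data.frame(X), offset = off)
  expect_equal(unname(fit$beta), unname(stats::coef(oracle)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se_beta),
               unname(summary(oracle)$coefficients[, 2]), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(oracle)),
               tolerance = 1e-8)
  expect_error(fit_poisson(cbind(X, X[, 2]), yy), "rank")
})

test_that("negative-binomial fit recovers dispersion and nests Poisson", {
  X <- small_design(5000, seed = 10)
  off <- log(fertcount:::with_seed(11, stats::runif(5000, 0.5, 3)))
  y <- simulate_counts("negbin", X, c(0.4, 0.3, -0.3), offset = off,
                       r = 2, seed = 12)
  fit <- fit_negbin(X, y, off)
  expect_true(fit$converged)
  expect_lt(abs(fit$r - 2) / 2, 0.2)
  expect_true(all(abs(fit$beta - c(0.4, 0.3, -0.3)) < 3 * fit$se_beta))
  expect_gte(fit$loglik, fit_poisson(X, y, off)$loglik)
  # independent oracle: MASS::glm.nb on the same data
  skip_if_not_installed("MASS")
  oracle <- MASS::glm.nb(y ~ x1 + x2 + offset(off),
                         data = data.frame(as.data.frame(X), off = off))
  expect_equal(unname(fit$beta), unname(stats::coef(oracle)),
               tolerance = 1e-4)
  expect_equal(fit$r, oracle$theta, tolerance = 1e-3)
})

test_that("data without overdispersion drive the NB dispersion to its cap", {
  # constant counts: sample variance below the mean, no overdispersion at
  # all, so the profile likelihood increases in r all the way to the cap
  n <- 500
  X1 <- matrix(1, n, 1, dimnames = list(NULL, "Intercept"))
  y <- rep(2L, n)
  fit <- fit_negbin(X1, y)
  expect_true("r_cap" %in% fit$boundary_flags)
  expect_equal(fit$r, 1e6)
  # at the boundary NB and Poisson agree
  pois <- fit_poisson(X1, y)
  expect_equal(unname(fit$beta), unname(pois$beta), tolerance = 1e-5)
  expect_equal(fit$loglik, pois$loglik, tolerance = 1e-4)
})

test_that("zero-inflated fits recover their generating parameters", {
  X <- small_design(5000, seed = 15)
  off <- log(fertcount:::with_seed(16, stats::runif(5000, 0.5, 3)))
  beta <- c(0.3, 0.25, -0.35); gam <- c(-0.6, 0.5, 0.4)
  y <- simulate_counts("zip", X, beta, offset = off, gamma = gam, seed = 17)
  fit <- fit_zip(X, y, off)
  expect_true(fit$converged)
  expect_true(all(abs(fit$beta - beta) < 3 * fit$se_beta))
  expect_true(all(abs(fit$gamma - gam) < 3 * fit$se_gamma))
  expect_gte(fit$loglik, fit_poisson(X, y, off)$loglik)

  yz <- simulate_counts("zinb", X, beta, offset = off, gamma = gam,
                        r = 1.5, seed = 18)
  fitz <- fit_zinb(X, yz, off)
  expect_true(fitz$converged)
  expect_true(all(abs(fitz$beta - beta) < 3 * fitz$se_beta))
  expect_true(all(abs(fitz$gamma - gam) < 3 * fitz$se_gamma))
  expect_lt(abs(fitz$r - 1.5) / 1.5, 0.5)
})

test_that("boundary cases of the inflation part are flagged", {
  X <- small_design(500, seed = 19)
  y <- simulate_counts("poisson", X, c(2.5, 0.1, 0.1), seed = 20)
  stopifnot(sum(y == 0) == 0)
  fit <- fit_zip(X, y)
  expect_true("no_zeros" %in% fit$boundary_flags)
  theta <- stats::plogis(drop(X %*% fit$gamma))
  expect_lte(max(theta), 1e-6)
})

test_that("ZINB collapses to NB when there is no extra inflation", {
  X <- small_design(3000, seed = 21)
  y <- simulate_counts("negbin", X, c(0.5, 0.3, -0.2), r = 2, seed = 22)
  nb <- fit_negbin(X, y)
  zinb <- fit_zinb(X, y)
  # the extra inflation part may absorb a little zero mass in a finite
  # sample; the count coefficients must agree within statistical precision
  expect_true(all(abs(zinb$beta - nb$beta) < 3 * nb$se_beta))
  expect_gte(zinb$loglik, nb$loglik - 1e-6)
  expect_lt(zinb$loglik - nb$loglik, 3)
})

test_that("the log-likelihood nesting chain holds on a common fixture", {
  X <- small_design(2000, seed = 23)
  off <- log(fertcount:::with_seed(24, stats::runif(2000, 0.5, 2)))
  y <- simulate_counts("zinb", X, c(0.4, 0.2, -0.3), offset = off,
                       gamma = c(-0.8, 0.4, 0), r = 1.2, seed = 25)
  ll <- sapply(c("poisson", "negbin", "zip", "zinb"), function(f)
    fit_count_model(f, X, y, off)$loglik)
  expect_lte(ll["poisson"], ll["zip"] + 1e-6)
  expect_lte(ll["poisson"], ll["negbin"] + 1e-6)
  expect_lte(ll["negbin"], ll["zinb"] + 1e-6)
  expect_lte(ll["zip"], ll["zinb"] + 1e-6)
})

test_that("the score vanishes at every reported MLE", {
  # each family fitted to data from its own process (interior optimum)
  X <- small_design(1500, seed = 26)
  off <- log(fertcount:::with_seed(27, stats::runif(1500, 0.5, 2)))
  beta <- c(0.4, 0.2, -0.3); gam <- c(-0.5, 0.3, 0.2)
  ys <- list(
    poisson = simulate_counts("poisson", X, beta, offset = off, seed = 28),
    negbin = simulate_counts("negbin", X, beta, offset = off, r = 1.5,
                             seed = 28),
    zip = simulate_counts("zip", X, beta, offset = off, gamma = gam,
                          seed = 28),
    zinb = simulate_counts("zinb", X, beta, offset = off, gamma = gam,
                           r = 1.5, seed = 28))
  for (fam in c("poisson", "negbin", "zip", "zinb")) {
    y <- ys[[fam]]
    fit <- fit_count_model(fam, X, y, off)
    par <- switch(fam,
                  poisson = fit$beta,
                  negbin = c(fit$beta, log(fit$r)),
                  zip = c(fit$beta, fit$gamma),
                  zinb = c(fit$beta, fit$gamma, log(fit$r)))
    g <- fertcount:::.nll_fns(fam, X, y, off)$grad(par)
    expect_lt(max(abs(g)), 1e-6)
  }
})

test_that("model comparison enforces the AIC identity on shared data", {
  X <- small_design(2000, seed = 30)
  y <- simulate_counts("zip", X, c(0.5, 0.2, -0.2),
                       gamma = c(-0.3, 0, 0), seed = 31)
  fits <- list(fit_poisson(X, y), fit_zip(X, y))
  tab <- compare_models(fits)
  expect_equal(tab$aic, -2 * tab$loglik + 2 * tab$k)
  # residual mean equals the direct recomputation
  mu <- exp(drop(X %*% fits[[1]]$beta))
  expect_equal(tab$resid_mean[1], mean(y - mu), tolerance = 1e-8)
  # ZIP beats Poisson on ZIP-generated data, as in the motivating analysis
  expect_lt(tab$aic[2], tab$aic[1])
  # fits on different data are refused
  other <- fit_poisson(X[1:1000, ], y[1:1000])
  expect_error(compare_models(list(fits[[1]], other)), "identical data")
})

test_that("coefficient summaries carry Wald inference", {
  X <- small_design(800, seed = 32)
  y <- simulate_counts("poisson", X, c(0.5, 0.4, 0), seed = 33)
  s <- summary(fit_poisson(X, y))
  expect_equal(nrow(s), 3L)
  expect_equal(s$z, s$estimate / s$se)
  expect_equal(s$p, 2 * stats::pnorm(-abs(s$z)))
  expect_true(all(s$code %in% c("***", "**", "*", ".", " ")))
})
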