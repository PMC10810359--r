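#' Configuration for Bayesian Poisson regression by MCMC
#'
#' Settings for [sample_posterior()]: three chains of 1,000 iterations
#' with a 100-iteration burn-in by default, and independent normal priors
#' `beta_j ~ N(prior_mean, .)` on every coefficient.  The prior scale
#' `1e-3` is read as a *precision* by default (variance 1,000 — a vague
#' prior under which posterior means track the MLEs); set
#' `prior_interpretation = "variance"` for the literal variance-1e-3
#' reading.
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain.
#' @param burn_in discarded initial iterations (`< n_iter`); proposal
#'   adaptation happens only here.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param prior_mean,prior_precision normal prior parameters.
#' @param prior_interpretation `"precision"` (default) or `"variance"`.
#' @param step_scale `"auto"` (2.4 x the MLE standard errors) or a
#'   positive multiplier applied to them.
#' @param seed integer master seed.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 1000L, burn_in = 100L,
                        thin = 1L, prior_mean = 0, prior_precision = 1e-3,
                        prior_interpretation = c("precision", "variance"),
                        step_scale = "auto", seed = 1L) {
  prior_interpretation <- match.arg(prior_interpretation)
  stopifnot(n_chains >= 1, n_iter > burn_in, burn_in >= 0, thin >= 1,
            prior_precision > 0)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 prior_mean = prior_mean, prior_precision = prior_precision,
                 prior_interpretation = prior_interpretation,
                 step_scale = step_scale, seed = as.integer(seed)),
            class = "mcmc_config")
}

.prior_tau <- function(config) {
  if (config$prior_interpretation == "precision") config$prior_precision
  else 1 / config$prior_precision
}

#' Log posterior density of the Bayesian Poisson regression
#'
#' Poisson log-likelihood (including the `lfactorial(y)` terms) plus the
#' sum of independent normal prior log-densities on the coefficients.
#'
#' @param beta coefficient vector (length `ncol(X)`).
#' @param X design matrix.
#' @param y nonnegative integer response.
#' @param offset log exposure (default zero).
#' @param config an [mcmc_config()] carrying the prior.
#' @return Log posterior (finite for finite `beta`).
#' @export
log_posterior <- function(beta, X, y, offset = NULL, config = mcmc_config()) {
  d <- .check_xy(X, y, offset)
  if (length(beta) != ncol(d$X))
    stop("length(beta) != ncol(X)", call. = FALSE)
  eta <- d$offset + drop(d$X %*% beta)
  tau <- .prior_tau(config)
  sum(d$y * eta - exp(eta) - lfactorial(d$y)) +
    sum(stats::dnorm(beta, config$prior_mean, 1 / sqrt(tau), log = TRUE))
}

#' Sample the posterior of a Poisson regression by adaptive
#' random-walk Metropolis
#'
#' Runs `n_chains` independent componentwise random-walk Metropolis
#' chains.  Chains start at the maximum-likelihood estimate (jittered per
#' chain) and proposal standard deviations start at 2.4 x the MLE standard
#' errors; during burn-in each component's step is rescaled every 20
#' iterations towards a 0.44 acceptance rate, and adaptation is frozen
#' afterwards so the kept draws target the exact posterior.  Fully
#' reproducible given `config$seed`.
#'
#' @inheritParams log_posterior
#' @param config an [mcmc_config()].
#' @return Object of class `fert_mcmc`: list with `draws` (array
#'   `chains x kept x p`), `param_names`, per-chain `acceptance_rate`
#'   (post-burn-in), the final `step` sizes and the `config`.
#' @export
sample_posterior <- function(X, y, offset = NULL, config = mcmc_config()) {
  d <- .check_xy(X, y, offset)
  X <- d$X; y <- d$y; off <- d$offset
  p <- ncol(X)
  tau <- .prior_tau(config)
  pm <- config$prior_mean
  mle <- fit_poisson(X, y, off)
  se <- mle$se_beta
  se[!is.finite(se) | se <= 0] <- 0.1
  step0 <- if (identical(config$step_scale, "auto")) 2.4 * se
           else config$step_scale * se
  lf <- sum(lfactorial(y))

  kept_iters <- seq.int(config$burn_in + config$thin, config$n_iter,
                        by = config$thin)
  draws <- array(NA_real_,
                 dim = c(config$n_chains, length(kept_iters), p),
                 dimnames = list(NULL, NULL, colnames(X)))
  acc_rate <- numeric(config$n_chains)
  steps <- matrix(NA_real_, config$n_chains, p)

  for (ch in seq_len(config$n_chains)) {
    res <- with_seed(derive_seed(config$seed, 1000L + ch), {
      beta <- mle$beta + stats::rnorm(p, 0, se)
      eta <- off + drop(X %*% beta)
      lp_lik <- sum(y * eta - exp(eta)) - lf
      lp_pri <- stats::dnorm(beta, pm, 1 / sqrt(tau), log = TRUE)
      step <- step0
      acc_post <- 0L
      n_post <- 0L
      blk_acc <- integer(p)
      keep <- matrix(NA_real_, length(kept_iters), p)
      ki <- 1L
      for (it in seq_len(config$n_iter)) {
        for (j in seq_len(p)) {
          dlt <- stats::rnorm(1, 0, step[j])
          eta_new <- eta + X[, j] * dlt
          lp_lik_new <- sum(y * eta_new - exp(eta_new)) - lf
          lp_pri_new <- stats::dnorm(beta[j] + dlt, pm, 1 / sqrt(tau),
                                     log = TRUE)
          if (log(stats::runif(1)) <
              (lp_lik_new + lp_pri_new) - (lp_lik + lp_pri[j])) {
            beta[j] <- beta[j] + dlt
            eta <- eta_new
            lp_lik <- lp_lik_new
            lp_pri[j] <- lp_pri_new
            if (it <= config$burn_in) blk_acc[j] <- blk_acc[j] + 1L
            else acc_post <- acc_post + 1L
          }
          if (it > config$burn_in) n_post <- n_post + 1L
        }
        if (it <= config$burn_in && it %% 20L == 0L) {
          step <- step * exp(blk_acc / 20 - 0.44)
          blk_acc <- integer(p)
        }
        if (ki <= length(kept_iters) && it == kept_iters[ki]) {
          keep[ki, ] <- beta
          ki <- ki + 1L
        }
      }
      list(keep = keep, acc = acc_post / max(n_post, 1L), step = step)
    })
    draws[ch, , ] <- res$keep
    acc_rate[ch] <- res$acc
    steps[ch, ] <- res$step
  }
  structure(list(draws = draws, param_names = colnames(X),
                 acceptance_rate = acc_rate, step = steps, config = config),
            class = "fert_mcmc")
}

#' @export
print.fert_mcmc <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior draws: %d chain(s) x %d kept iterations x %d parameters\n",
              d[1], d[2], d[3]))
  cat(sprintf("  acceptance rate: %s\n",
              paste(sprintf("%.2f", x$acceptance_rate), collapse = ", ")))
  invisible(x)
}

# Flatten a fert_mcmc / array / matrix into a draws x p matrix.
.draw_matrix <- function(draws) {
  if (inherits(draws, "fert_mcmc")) draws <- draws$draws
  if (is.matrix(draws)) return(draws)
  if (is.array(draws) && length(dim(draws)) == 3L) {
    d <- dim(draws)
    out <- matrix(aperm(draws, c(2, 1, 3)), d[1] * d[2], d[3])
    colnames(out) <- dimnames(draws)[[3]]
    return(out)
  }
  matrix(draws, ncol = 1)
}

# Per-parameter chains as a list of (iterations x chains) matrices.
.chain_list <- function(draws) {
  if (inherits(draws, "fert_mcmc")) draws <- draws$draws
  if (is.numeric(draws) && is.null(dim(draws)))
    return(list(matrix(draws, ncol = 1)))
  if (is.matrix(draws)) return(list(draws))
  d <- dim(draws)
  lapply(seq_len(d[3]), function(j) t(draws[, , j, drop = TRUE]))
}

#' Lag-l autocorrelation of a chain
#'
#' The correlation between every sample and the sample `lag` steps
#' earlier, computed as the Pearson correlation of the two offset slices
#' of the chain.
#'
#' @param chain numeric vector of draws.
#' @param lag nonnegative lag, smaller than the chain length.
#' @return Autocorrelation in \[-1, 1\]; 1 at lag 0; `NaN` (with a
#'   warning) for a constant chain.
#' @export
autocorrelation <- function(chain, lag) {
  n <- length(chain)
  if (lag < 0 || lag >= n) stop("lag must satisfy 0 <= lag < length(chain)",
                                call. = FALSE)
  if (stats::var(chain) == 0) {
    warning("constant chain: autocorrelation undefined")
    return(NaN)
  }
  if (lag == 0) return(1)
  a <- chain[seq_len(n - lag)]
  b <- chain[seq_len(n - lag) + lag]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NaN)
  stats::cor(a, b)
}

#' Effective sample size of (possibly several) MCMC chains
#'
#' `N / (1 + 2 * sum_l rho_l)` with the autocorrelation sum truncated by
#' the initial-positive-sequence rule: consecutive lag pairs
#' `rho_{2k} + rho_{2k+1}` are accumulated until the first nonpositive
#' pair.  With several chains the per-lag autocorrelations are averaged
#' across chains and `N` is the total number of draws.  The result is
#' capped at `N`.
#'
#' @param chains numeric vector (one chain), matrix (iterations x chains)
#'   or a one-parameter slice of a `fert_mcmc` draws array.
#' @return Effective number of independent draws.
#' @export
effective_sample_size <- function(chains) {
  if (is.numeric(chains) && is.null(dim(chains)))
    chains <- matrix(chains, ncol = 1)
  m <- as.matrix(chains)
  n <- nrow(m)
  if (n < 10) stop("need at least 10 draws per chain", call. = FALSE)
  if (all(apply(m, 2, stats::var) == 0))
    stop("constant chains: ESS undefined", call. = FALSE)
  N <- n * ncol(m)
  rho <- function(l) mean(apply(m, 2, autocorrelation, lag = l), na.rm = TRUE)
  tau <- -1
  k <- 0L
  repeat {
    l1 <- 2L * k
    l2 <- 2L * k + 1L
    if (l2 >= n - 1L) break
    gam <- (if (l1 == 0L) 1 else rho(l1)) + rho(l2)
    if (!is.finite(gam) || gam <= 0) break
    tau <- tau + 2 * gam
    k <- k + 1L
  }
  tau <- max(tau, 1 / N)
  min(N / tau, N)
}

#' Deviance information criterion for the Bayesian Poisson regression
#'
#' `D(beta) = -2 logLik(beta)`; the mean deviance is the average of `D`
#' over the posterior draws, the penalty (effective number of parameters)
#' is `pD = mean deviance - D(posterior mean)`, and the penalized
#' deviance (the DIC) is their sum.
#'
#' @param draws a `fert_mcmc`, a 3-d draws array or a draws x p matrix.
#' @inheritParams log_posterior
#' @return Named vector `c(mean_deviance, penalty, penalized_deviance)`;
#'   `penalized_deviance = mean_deviance + penalty` by construction.
#' @export
dic <- function(draws, X, y, offset = NULL) {
  d <- .check_xy(X, y, offset)
  B <- .draw_matrix(draws)
  if (nrow(B) == 0) stop("no draws", call. = FALSE)
  dev <- function(beta) {
    eta <- d$offset + drop(d$X %*% beta)
    -2 * sum(d$y * eta - exp(eta) - lfactorial(d$y))
  }
  dbar <- mean(apply(B, 1, dev))
  pd <- dbar - dev(colMeans(B))
  c(mean_deviance = dbar, penalty = pd, penalized_deviance = dbar + pd)
}

#' Posterior summary table with MCMC diagnostics
#'
#' Per-coefficient posterior mean, standard deviation and effective
#' sample size, computed on the post-burn-in draws.
#'
#' @param object a `fert_mcmc`.
#' @param ... unused.
#' @return data.frame with columns `term`, `mean`, `sd`, `ess`.
#' @export
summary.fert_mcmc <- function(object, ...) {
  flat <- .draw_matrix(object)
  per_param <- .chain_list(object)
  data.frame(
    term = object$param_names,
    mean = colMeans(flat),
    sd = apply(flat, 2, stats::sd),
    ess = vapply(per_param, effective_sample_size, numeric(1)),
    row.names = NULL
  )
}
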