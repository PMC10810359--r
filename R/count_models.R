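# Maximum-likelihood machinery for the four birth-count regression
# families.  The count part always uses a log link with an additive
# log-exposure offset; the zero-inflation part uses a logit link without
# offset.  All fits are polished to a first-order optimum (max score
# component < 1e-8 away from parameter-space boundaries) and standard
# errors come from the observed information matrix.

.FAMILIES <- c("poisson", "negbin", "zip", "zinb")
.R_CAP <- 1e6
.MAX_ABS_GAMMA <- 20

.check_xy <- function(X, y, offset) {
  X <- as.matrix(X)
  stop_if_not_count(y, "y")
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)", call. = FALSE)
  if (is.null(offset)) offset <- numeric(length(y))
  if (length(offset) != length(y))
    stop("offset must have the same length as y", call. = FALSE)
  list(X = X, y = as.numeric(y), offset = as.numeric(offset))
}

.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

# --- per-family negative log-likelihoods and analytic gradients ---------
# Parameter packing: poisson beta; negbin c(beta, log r);
# zip c(beta, gamma); zinb c(beta, gamma, log r).

.nll_fns <- function(family, X, y, offset) {
  p <- ncol(X)
  lf <- lfactorial(y)
  zero <- y == 0
  pos <- !zero
  switch(family,
    poisson = list(
      nll = function(par) {
        eta <- offset + drop(X %*% par)
        sum(exp(eta) - y * eta + lf)
      },
      grad = function(par) {
        mu <- exp(offset + drop(X %*% par))
        drop(crossprod(X, mu - y))
      }),
    negbin = list(
      nll = function(par) {
        r <- exp(par[p + 1L])
        mu <- exp(offset + drop(X %*% par[1:p]))
        -sum(lgamma(y + r) - lgamma(r) - lf + r * (log(r) - log(r + mu)) +
               y * (log(mu) - log(r + mu)))
      },
      grad = function(par) {
        r <- exp(par[p + 1L])
        mu <- exp(offset + drop(X %*% par[1:p]))
        gb <- -drop(crossprod(X, (y - mu) * r / (r + mu)))
        gr <- -r * sum(digamma(y + r) - digamma(r) + log(r) - log(r + mu) +
                         (mu - y) / (r + mu))
        c(gb, gr)
      }),
    zip = list(
      nll = function(par) {
        eta <- offset + drop(X %*% par[1:p])
        mu <- exp(eta)
        s <- drop(X %*% par[(p + 1L):(2L * p)])
        lth <- stats::plogis(s, log.p = TRUE)
        l1m <- stats::plogis(-s, log.p = TRUE)
        ll <- numeric(length(y))
        ll[zero] <- .logsumexp2(lth[zero], l1m[zero] - mu[zero])
        ll[pos] <- l1m[pos] + y[pos] * eta[pos] - mu[pos] - lf[pos]
        -sum(ll)
      },
      grad = function(par) {
        eta <- offset + drop(X %*% par[1:p])
        mu <- exp(eta)
        s <- drop(X %*% par[(p + 1L):(2L * p)])
        lth <- stats::plogis(s, log.p = TRUE)
        l1m <- stats::plogis(-s, log.p = TRUE)
        theta <- exp(lth)
        deta <- ds <- numeric(length(y))
        l0 <- .logsumexp2(lth[zero], l1m[zero] - mu[zero])
        A <- exp(l1m[zero] - mu[zero] - l0)      # (1-theta)e^{-mu}/p0
        deta[zero] <- -A * mu[zero]
        ds[zero] <- exp(lth[zero] + l1m[zero] - l0) * (1 - exp(-mu[zero]))
        deta[pos] <- y[pos] - mu[pos]
        ds[pos] <- -theta[pos]
        -c(drop(crossprod(X, deta)), drop(crossprod(X, ds)))
      }),
    zinb = list(
      nll = function(par) {
        r <- exp(par[2L * p + 1L])
        mu <- exp(offset + drop(X %*% par[1:p]))
        s <- drop(X %*% par[(p + 1L):(2L * p)])
        lth <- stats::plogis(s, log.p = TRUE)
        l1m <- stats::plogis(-s, log.p = TRUE)
        lq <- r * (log(r) - log(r + mu))          # log P(NB = 0)
        ll <- numeric(length(y))
        ll[zero] <- .logsumexp2(lth[zero], l1m[zero] + lq[zero])
        ll[pos] <- l1m[pos] + lgamma(y[pos] + r) - lgamma(r) - lf[pos] +
          lq[pos] + y[pos] * (log(mu[pos]) - log(r + mu[pos]))
        -sum(ll)
      },
      grad = function(par) {
        r <- exp(par[2L * p + 1L])
        mu <- exp(offset + drop(X %*% par[1:p]))
        s <- drop(X %*% par[(p + 1L):(2L * p)])
        lth <- stats::plogis(s, log.p = TRUE)
        l1m <- stats::plogis(-s, log.p = TRUE)
        theta <- exp(lth)
        lq <- r * (log(r) - log(r + mu))
        deta <- ds <- dlr <- numeric(length(y))
        l0 <- .logsumexp2(lth[zero], l1m[zero] + lq[zero])
        D <- exp(l1m[zero] + lq[zero] - l0)       # (1-theta)q/p0
        mz <- mu[zero]
        deta[zero] <- -D * r * mz / (r + mz)
        ds[zero] <- exp(lth[zero] + l1m[zero] - l0) * (1 - exp(lq[zero]))
        dlr[zero] <- D * r * (log(r) - log(r + mz) + mz / (r + mz))
        mp <- mu[pos]
        deta[pos] <- (y[pos] - mp) * r / (r + mp)
        ds[pos] <- -theta[pos]
        dlr[pos] <- r * (digamma(y[pos] + r) - digamma(r) + log(r) -
                           log(r + mp) + (mp - y[pos]) / (r + mp))
        -c(drop(crossprod(X, deta)), drop(crossprod(X, ds)), sum(dlr))
      })
  )
}

#' Negative log-likelihood of a count regression family
#'
#' Evaluates the exact negative log-likelihood (including the
#' `lfactorial(y)` terms) of the Poisson, negative-binomial, zero-inflated
#' Poisson or zero-inflated negative-binomial regression, with
#' `mu_i = exp(offset_i + x_i' beta)` and, for the inflated families,
#' structural-zero probability `theta_i = plogis(x_i' gamma)`.
#'
#' @param family one of `"poisson"`, `"negbin"`, `"zip"`, `"zinb"`.
#' @param params packed parameter vector: `beta` (poisson),
#'   `c(beta, log(r))` (negbin), `c(beta, gamma)` (zip),
#'   `c(beta, gamma, log(r))` (zinb), where `beta` and `gamma` have
#'   `ncol(X)` entries each.
#' @param X numeric design matrix.
#' @param y nonnegative integer response.
#' @param offset log-exposure offset (default zero).
#' @return The negative log-likelihood (a finite scalar for admissible
#'   parameters).
#' @export
neg_log_likelihood <- function(family, params, X, y, offset = NULL) {
  family <- match.arg(family, .FAMILIES)
  d <- .check_xy(X, y, offset)
  p <- ncol(d$X)
  expect <- switch(family, poisson = p, negbin = p + 1L, zip = 2L * p,
                   zinb = 2L * p + 1L)
  if (length(params) != expect)
    stop(sprintf("params must have length %d for family '%s'",
                 expect, family), call. = FALSE)
  .nll_fns(family, d$X, d$y, d$offset)$nll(params)
}

# Newton polish to a first-order optimum; returns par, hessian, converged.
.polish <- function(par, fns, max_iter = 25L, tol = 1e-8) {
  H <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- fns$grad(par)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- stats::optimHess(par, fns$nll, fns$grad)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    f0 <- fns$nll(par)
    lambda <- 1
    repeat {
      cand <- par - lambda * step
      f1 <- fns$nll(cand)
      if (is.finite(f1) && f1 <= f0 + 1e-12) { par <- cand; break }
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    if (lambda < 1e-10) break
  }
  if (is.null(H)) H <- stats::optimHess(par, fns$nll, fns$grad)
  list(par = par, hessian = H, converged = converged)
}

.se_from_hessian <- function(H) {
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(rep(NA_real_, nrow(H)))
  d <- diag(V)
  d[!is.finite(d) | d <= 0] <- NA_real_
  sqrt(d)
}

.new_fit <- function(family, beta, se_beta, gamma = NULL, se_gamma = NULL,
                     r = NULL, se_log_r = NULL, loglik, X, y, offset,
                     converged, boundary = character(0)) {
  theta <- if (!is.null(gamma)) stats::plogis(drop(X %*% gamma))
  mu <- exp(offset + drop(X %*% beta))
  ey <- if (is.null(theta)) mu else mu * (1 - theta)
  k <- length(beta) + length(gamma) + as.integer(!is.null(r))
  res <- y - ey
  structure(list(
    family = family,
    beta = stats::setNames(beta, colnames(X)),
    se_beta = stats::setNames(se_beta, colnames(X)),
    gamma = if (!is.null(gamma)) stats::setNames(gamma, colnames(X)),
    se_gamma = if (!is.null(se_gamma)) stats::setNames(se_gamma, colnames(X)),
    r = if (!is.null(r)) unname(r), se_log_r = unname(se_log_r),
    loglik = unname(loglik), k = k, aic = unname(-2 * loglik + 2 * k),
    residual_summary = c(min = min(res), mean = mean(res), max = max(res)),
    converged = converged, boundary_flags = boundary,
    n = length(y),
    fingerprint = c(n = length(y), sum_y = sum(y), sum_offset = sum(offset),
                    sum_x = sum(X))
  ), class = "fert_fit")
}

.check_rank <- function(X) {
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
}

#' Fit a Poisson regression with log-exposure offset
#'
#' Iteratively reweighted least squares to the maximum-likelihood
#' estimate, with observed-information standard errors.  Convergence is
#' declared when the relative log-likelihood change falls below 1e-8 (and
#' the score is polished below 1e-8 in absolute value).
#'
#' @param X full-rank numeric design matrix (n x p, n > p).
#' @param y nonnegative integer response.
#' @param offset log exposure; default zero.
#' @return A `fert_fit` object; see [summary.fert_fit()].
#' @export
fit_poisson <- function(X, y, offset = NULL) {
  d <- .check_xy(X, y, offset)
  X <- d$X; y <- d$y; off <- d$offset
  .check_rank(X)
  fns <- .nll_fns("poisson", X, y, off)
  mu <- pmax(y, 0) + 0.5
  eta <- log(mu)
  beta <- NULL
  ll_old <- -Inf
  converged <- FALSE
  for (it in 1:100) {
    z <- eta - off + (y - mu) / mu
    wsq <- sqrt(mu)
    fit <- stats::lm.fit(X * wsq, z * wsq)
    beta <- fit$coefficients
    eta <- off + drop(X %*% beta)
    mu <- exp(eta)
    ll <- -fns$nll(beta)
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-8 * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  pol <- .polish(beta, fns)
  beta <- pol$par
  se <- .se_from_hessian(pol$hessian)
  .new_fit("poisson", beta, se, loglik = -fns$nll(beta), X = X, y = y,
           offset = off, converged = converged || pol$converged)
}

#' Fit a negative-binomial regression with log-exposure offset
#'
#' Joint maximum likelihood of the regression coefficients and the
#' dispersion parameter `r` (variance `mu + mu^2 / r`; the Poisson is the
#' `r -> Inf` limit), by alternating an IRLS update of `beta` given `r`
#' with a one-dimensional profile update of `r` given `beta`, then
#' polishing to the joint optimum.  Near-equidispersed data drive `r` to
#' the cap 1e6, reported with the `"r_cap"` boundary flag.
#'
#' @inheritParams fit_poisson
#' @return A `fert_fit` object.
#' @export
fit_negbin <- function(X, y, offset = NULL) {
  d <- .check_xy(X, y, offset)
  X <- d$X; y <- d$y; off <- d$offset
  .check_rank(X)
  fns <- .nll_fns("negbin", X, y, off)
  beta <- fit_poisson(X, y, off)$beta
  lr <- 0
  ll_old <- -Inf
  converged <- FALSE
  for (it in 1:100) {
    # profile r given beta
    opt <- stats::optimize(function(l) fns$nll(c(beta, l)),
                           interval = c(log(1e-4), log(.R_CAP)),
                           tol = 1e-10)
    lr <- opt$minimum
    # IRLS beta given r (Fisher scoring for the NB log link)
    r <- exp(lr)
    for (j in 1:5) {
      eta <- off + drop(X %*% beta)
      mu <- exp(eta)
      w <- mu * r / (r + mu)
      z <- eta - off + (y - mu) / mu
      beta <- stats::lm.fit(X * sqrt(w), z * sqrt(w))$coefficients
    }
    ll <- -fns$nll(c(beta, lr))
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-8 * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  boundary <- character(0)
  if (lr > log(.R_CAP) - 0.01) {
    boundary <- "r_cap"
    lr <- log(.R_CAP)
    # at the boundary the information for r is degenerate: polish and
    # report SEs for beta only, holding r fixed
    pfns <- list(nll = function(b) fns$nll(c(b, lr)),
                 grad = function(b) fns$grad(c(b, lr))[seq_along(b)])
    pol <- .polish(beta, pfns)
    beta <- pol$par
    se <- .se_from_hessian(pol$hessian)
    return(.new_fit("negbin", beta, se, r = exp(lr), se_log_r = NA_real_,
                    loglik = -fns$nll(c(beta, lr)), X = X, y = y,
                    offset = off, converged = converged, boundary = boundary))
  }
  pol <- .polish(c(beta, lr), fns)
  par <- pol$par
  se <- .se_from_hessian(pol$hessian)
  p <- ncol(X)
  .new_fit("negbin", par[1:p], se[1:p], r = exp(par[p + 1L]),
           se_log_r = se[p + 1L], loglik = -fns$nll(par), X = X, y = y,
           offset = off, converged = converged || pol$converged,
           boundary = boundary)
}

# Shared fitting core for the two zero-inflated families.
.fit_inflated <- function(family, X, y, off) {
  fns <- .nll_fns(family, X, y, off)
  p <- ncol(X)
  nb <- family == "zinb"
  count_start <- if (nb) fit_negbin(X, y, off) else fit_poisson(X, y, off)
  lr0 <- if (nb) log(min(max(count_start$r, 1e-3), 100)) else NULL
  boundary <- character(0)

  if (!any(y == 0)) {
    # no zeros: the inflation intercept diverges to -Inf; cap theta near 0
    gamma <- c(stats::qlogis(1e-8), rep(0, p - 1L))
    beta <- count_start$beta
    par <- c(beta, gamma, lr0)
    return(.new_fit(family, beta, count_start$se_beta, gamma,
                    rep(NA_real_, p),
                    r = if (nb) count_start$r,
                    se_log_r = if (nb) NA_real_,
                    loglik = -fns$nll(par), X = X, y = y, offset = off,
                    converged = TRUE, boundary = "no_zeros"))
  }

  # warm start: count part from the uninflated fit, inflation part from a
  # logistic regression of the zero indicator
  g0 <- suppressWarnings(
    stats::glm.fit(X, as.numeric(y == 0),
                   family = stats::binomial())$coefficients)
  g0[!is.finite(g0)] <- 0
  g0 <- pmin(pmax(g0, -.MAX_ABS_GAMMA / 2), .MAX_ABS_GAMMA / 2)
  par0 <- c(count_start$beta, g0, lr0)
  opt <- stats::optim(par0, fns$nll, fns$grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  pol <- .polish(opt$par, fns)
  par <- pol$par
  gamma <- par[(p + 1L):(2L * p)]
  theta_hat <- stats::plogis(drop(X %*% gamma))
  if (any(abs(gamma) > .MAX_ABS_GAMMA)) boundary <- c(boundary, "separation")
  if (max(theta_hat) <= 1e-6) boundary <- c(boundary, "theta_zero")
  se <- .se_from_hessian(pol$hessian)
  .new_fit(family, par[1:p], se[1:p], gamma, se[(p + 1L):(2L * p)],
           r = if (nb) exp(par[2L * p + 1L]),
           se_log_r = if (nb) se[2L * p + 1L],
           loglik = -fns$nll(par), X = X, y = y, offset = off,
           converged = opt$convergence == 0 || pol$converged,
           boundary = boundary)
}

#' Fit a zero-inflated Poisson regression
#'
#' Maximum likelihood for the mixture of a structural zero (probability
#' `theta_i = plogis(x_i' gamma)`, logit link, no offset) and a Poisson
#' count (`mu_i = exp(offset_i + x_i' beta)`), using the same predictors
#' in both parts.  Warm starts come from the Poisson fit and a logistic
#' regression of the zero indicator; BFGS with analytic gradients is
#' followed by a Newton polish.  Data without zeros are a boundary case:
#' `theta` is capped near zero and flagged `"no_zeros"`.
#'
#' @inheritParams fit_poisson
#' @return A `fert_fit` object with both `beta` and `gamma` parts.
#' @export
fit_zip <- function(X, y, offset = NULL) {
  d <- .check_xy(X, y, offset)
  .check_rank(d$X)
  .fit_inflated("zip", d$X, d$y, d$offset)
}

#' Fit a zero-inflated negative-binomial regression
#'
#' Same mixture contract as [fit_zip()] with a negative-binomial count
#' part (dispersion `r` estimated jointly on the log scale).
#'
#' @inheritParams fit_poisson
#' @return A `fert_fit` object with `beta`, `gamma` and `r`.
#' @export
fit_zinb <- function(X, y, offset = NULL) {
  d <- .check_xy(X, y, offset)
  .check_rank(d$X)
  .fit_inflated("zinb", d$X, d$y, d$offset)
}

#' Fit any of the four count-regression families
#'
#' @param family `"poisson"`, `"negbin"`, `"zip"` or `"zinb"`.
#' @inheritParams fit_poisson
#' @return A `fert_fit` object.
#' @export
fit_count_model <- function(family, X, y, offset = NULL) {
  family <- match.arg(family, .FAMILIES)
  switch(family,
         poisson = fit_poisson(X, y, offset),
         negbin = fit_negbin(X, y, offset),
         zip = fit_zip(X, y, offset),
         zinb = fit_zinb(X, y, offset))
}

#' Expected response of a fitted count model
#'
#' `E[y | x] = mu` for Poisson and negative binomial, `mu * (1 - theta)`
#' for the zero-inflated families — always nonnegative, which is the point
#' of modelling counts on the log scale rather than with a linear model.
#'
#' @param object a `fert_fit`.
#' @param X design matrix of new observations.
#' @param offset log exposure for the new observations (default zero).
#' @param ... unused.
#' @return Numeric vector of expected counts.
#' @export
predict.fert_fit <- function(object, X, offset = NULL, ...) {
  X <- as.matrix(X)
  if (is.null(offset)) offset <- numeric(nrow(X))
  mu <- exp(offset + drop(X %*% object$beta))
  if (!is.null(object$gamma))
    mu <- mu * (1 - stats::plogis(drop(X %*% object$gamma)))
  mu
}

#' Mean and variance of the zero-inflated Poisson response
#'
#' Moments implied by the ZIP mixture pmf: `E(y) = mu (1 - theta)` and
#' `Var(y) = mu (1 - theta) (1 + theta mu)`.
#'
#' @param mu nonnegative Poisson mean of the count component.
#' @param theta structural-zero probability in \[0, 1\].
#' @return Named vector `c(mean, variance)`.
#' @export
zip_moments <- function(mu, theta) {
  if (any(mu < 0)) stop("mu must be nonnegative", call. = FALSE)
  if (any(theta < 0 | theta > 1))
    stop("theta must lie in [0, 1]", call. = FALSE)
  m <- mu * (1 - theta)
  c(mean = m, variance = m * (1 + theta * mu))
}

#' Side-by-side comparison of fitted count models
#'
#' Tabulates log-likelihood, parameter count, AIC (`-2 logLik + 2k`) and
#' the response-residual summary (`y - E[y|x]`) for fits of different
#' families to the same data; fits on different data are refused.
#'
#' @param fits list of `fert_fit` objects on identical data.
#' @return data.frame keyed by family.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "fert_fit")))
  fp <- lapply(fits, `[[`, "fingerprint")
  if (!all(vapply(fp, function(f) isTRUE(all.equal(f, fp[[1]])), logical(1))))
    stop("fits were not made on identical data", call. = FALSE)
  out <- do.call(rbind, lapply(fits, function(f)
    data.frame(family = f$family, loglik = f$loglik, k = f$k, aic = f$aic,
               resid_min = f$residual_summary[["min"]],
               resid_mean = f$residual_summary[["mean"]],
               resid_max = f$residual_summary[["max"]])))
  rownames(out) <- NULL
  out
}

#' @export
print.fert_fit <- function(x, ...) {
  cat(sprintf("%s count regression (n = %d)\n", x$family, x$n))
  cat(sprintf("  logLik = %.2f, k = %d, AIC = %.2f%s\n", x$loglik, x$k,
              x$aic, if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$r)) cat(sprintf("  dispersion r = %.4g\n", x$r))
  if (length(x$boundary_flags))
    cat("  boundary:", paste(x$boundary_flags, collapse = ", "), "\n")
  cat("Count part:\n")
  print(round(x$beta, 4))
  if (!is.null(x$gamma)) {
    cat("Inflation part (logit):\n")
    print(round(x$gamma, 4))
  }
  invisible(x)
}

#' Coefficient table of a fitted count model
#'
#' @param object a `fert_fit`.
#' @param ... unused.
#' @return data.frame with columns `part` (`count`/`inflation`), `term`,
#'   `estimate`, `se`, `z`, `p` (two-sided normal) and the conventional
#'   significance `code`.
#' @export
summary.fert_fit <- function(object, ...) {
  row_block <- function(part, est, se) {
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(part = part, term = names(est), estimate = unname(est),
               se = unname(se), z = unname(z), p = unname(p),
               code = vapply(unname(p), function(pp)
                 if (is.na(pp)) "" else significance_code(pp), character(1)))
  }
  out <- row_block("count", object$beta, object$se_beta)
  if (!is.null(object$gamma))
    out <- rbind(out, row_block("inflation", object$gamma, object$se_gamma))
  rownames(out) <- NULL
  structure(out, family = object$family, loglik = object$loglik,
            aic = object$aic)
}
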