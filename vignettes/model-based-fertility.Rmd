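---
title: "Model-based estimation of fertility rates from birth-count regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based estimation of fertility rates from birth-count regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertcount)
```

## The estimation problem

Household surveys such as the DHS interview ever-married women about their
birth histories.  The classical *direct* estimators of fertility divide
observed births by observed woman-years of exposure.  When responses are
incomplete, or estimates are wanted for domains where few women were
interviewed, a *model-based* (predictive) alternative is attractive: fit a
regression of birth counts on socio-demographic and family-planning
covariates using the sampled women, predict the expected births of the
non-sampled women, and compute the fertility measures from the combined
observed-plus-predicted totals.  fertcount implements that pipeline
end-to-end, together with a synthetic-data generator that makes every
stage testable without access to restricted survey microdata.

## Fertility measures

For 5-year age groups $g = 0,\dots,6$ (ages 15–19 through 45–49), with
$B_g$ total births and $E_g$ woman-years of exposure inside a reference
window,

$$\mathrm{ASFR}_g = 1000\,B_g/E_g, \qquad
  \mathrm{TFR} = 5 \sum_g \mathrm{ASFR}_g / 1000,$$
$$\mathrm{GFR} = 1000\,\textstyle\sum_g B_g \big/ \sum_g E_g, \qquad
  \mathrm{GRR} = 5 \sum_g \mathrm{ASFR}_g P_g / 1000,$$

where $P_g$ is the proportion of female births in group $g$.  Two scaling
conventions are deliberate.  The TFR is reported in births *per woman*
(the division by 1,000 undoes the per-1,000 ASFR scaling); published
per-1,000 phrasing is numerically identical.  The GFR carries an explicit
factor 1,000 so that typical values land near 150–250 per 1,000
woman-years, the scale on which the measure is conventionally read.
$P_g$ is user-supplied (a scalar or a per-group vector): sex ratios at
birth belong to census or administrative sources, not to this package.
With $P_g \equiv 0.5$, $\mathrm{GRR} = \mathrm{TFR}/2$ exactly, a useful
invariant for testing.

## Person-years of exposure

All date arithmetic is at month resolution using the DHS century month
code (CMC), months since January 1900.  The reference window of $w$
months before an interview at CMC $t_0$ is the half-open interval
$(t_0 - w,\, t_0]$: the interview month counts, the month $w$ before does
not.  During calendar month $t$ a woman born in month $d$ has completed
$t - d - 1$ months of age (she has lived that many full months at the
start of month $t$); a woman whose interview-month age is exactly 240
months therefore spends her entire preceding window below age 20.  Age
groups are half-open in completed months, $[180 + 60g,\, 180 + 60(g+1))$,
and months outside $[180, 600)$ (ages 15 to 50) contribute nothing.
A woman's window can straddle one group boundary, so she is tallied
twice — once per group — and her dated births are assigned to the group
she occupies in the birth month, which is by construction a group where
she has positive exposure.  Exposure is computed by closed-form interval
intersection and is validated in the test suite against an independent
month-by-month tally.

Exposure below age 15 and above 50 is truncated rather than imputed;
as a consequence, group totals at the extreme ages can understate true
exposure in real data where birth histories extend beyond the window.
This is a known limitation of person-year tabulation from a bounded
window, and it is the main reason model-based ASFRs at extreme ages
deviate most from direct estimates.

## Count regression models

Birth counts per person-year row are modelled with a log link and the
log of exposure as an offset, so coefficients act on rates:

* **Poisson**: $y_i \sim \mathrm{Pois}(\mu_i)$,
  $\log \mu_i = o_i + x_i^\top\beta$.
* **Negative binomial**: dispersion $r > 0$ with
  $\mathrm{Var}(y_i) = \mu_i + \mu_i^2/r$; the Poisson is the
  $r \to \infty$ limit.
* **Zero-inflated Poisson (ZIP)**: a structural zero with probability
  $\theta_i = \mathrm{logit}^{-1}(x_i^\top\gamma)$, otherwise a Poisson
  count; both parts use the same predictors, the inflation part has no
  offset.  The mixture has $E(y_i) = \mu_i(1-\theta_i)$ and
  $\mathrm{Var}(y_i) = \mu_i(1-\theta_i)(1+\theta_i\mu_i)$, the moments
  implied by the pmf (the test suite confirms them by Monte Carlo).
* **ZINB**: the same logistic inflation wrapped around a negative-
  binomial count part.  This is the natural composition of the two
  extensions; it is the definition used everywhere in the package.

### Fitting and numerical choices

Poisson models are fitted by iteratively reweighted least squares; the
negative binomial alternates an IRLS update of $\beta$ given $r$ with a
one-dimensional profile search over $\log r$; the zero-inflated families
are maximized by BFGS with analytic gradients, warm-started from the
uninflated fit and a logistic regression of the zero indicator.  Every
fit is then polished by damped Newton steps until the largest score
component falls below $10^{-8}$, and standard errors come from the
inverse observed information at the optimum.  Convergence of the outer
iterations is declared at a relative log-likelihood change of $10^{-8}$
with at most 100 iterations.

Boundaries are capped and flagged rather than allowed to diverge:
$r$ at $10^6$ (`"r_cap"`, reported when the data show no overdispersion),
$\theta$ near zero when the data contain no zeros (`"no_zeros"`), and
inflation coefficients beyond $\pm 20$ on the logit scale
(`"separation"`).  The model-comparison table reports response residuals
$y - \hat E[y\,|\,x]$ (with $\hat E = \hat\mu(1-\hat\theta)$ for the
inflated families); their minimum of $-1$ for Poisson fits at
$\hat\mu \le 1$ is a recognisable signature of this residual choice.
AIC is always $-2\ell + 2k$ with $k$ the number of free parameters.

Effect interpretation uses the standard log-linear arithmetic:
$e^{\beta_j}$ as a relative rate, $e^{\beta_a - \beta_b}$ as a rate
ratio between two dummy levels, and $100(e^{\beta\Delta} - 1)$ as a
percentage change.  95% Wald intervals use the two-decimal multiplier
1.96 exactly, matching the convention of printed survey reports; other
levels use the exact normal quantile.  P-values are two-sided normal on
$\hat\beta/\mathrm{se}$.

## Bayesian Poisson regression

The Poisson model is re-estimated with independent normal priors
$\beta_j \sim N(0, \tau)$ where $\tau = 10^{-3}$ is read as a
*precision* (variance 1,000): under the variance reading the prior would
dominate the likelihood and posterior means could not track the MLEs,
which they demonstrably do under the vague reading.  Both readings are
selectable via `mcmc_config(prior_interpretation=)`.

The sampler is a componentwise adaptive random-walk Metropolis: three
chains of 1,000 iterations with a 100-iteration burn-in by default.
Chains start at the MLE (jittered), proposals start at 2.4 times the MLE
standard errors, and each component's step is rescaled every 20 burn-in
iterations towards the optimal one-dimensional acceptance rate of 0.44.
Adaptation freezes at the end of burn-in so the kept draws target the
exact posterior.  Diagnostics follow standard MCMC practice: lag-$l$
autocorrelation (the Pearson correlation of the chain with itself $l$
steps back), effective sample size
$N/(1 + 2\sum_l \rho_l)$ with the autocorrelation sum truncated at the
first nonpositive consecutive-lag pair (the initial-positive-sequence
rule; per-lag autocorrelations are averaged across chains), and the DIC
triple: mean posterior deviance $\bar D$, penalty
$p_D = \bar D - D(\bar\beta)$, and penalized deviance $\bar D + p_D$.
The single-chain Geyer ESS estimate has substantial Monte-Carlo spread
(of order 10–15% for strongly autocorrelated chains of length $10^4$);
multi-chain averaging is the package's default route to stabler values.

## The synthetic-data generator

`generate_population()` draws DHS-like woman records with known ground
truth so that parameter recovery, exposure conservation and the
design-based properties of the estimators can be verified exactly.  What
it emulates:

* the women's-recode variable set and codings (region, residence,
  education, wealth score, children/daughter counts, marriage-to-first-
  birth interval including the "no birth" code 996, contraceptive
  method, pregnancy termination, occupation, husband age), recoded to a
  fixed 25-column design with Punjab / "not using" / "not working" base
  categories;
* window birth counts from any of the four families with
  $\mu_i = e^{x_i^\top\beta}$ and, for the inflated families,
  $\theta_i = \mathrm{logit}^{-1}(x_i^\top\gamma)$.  The default
  coefficient vectors reproduce the coefficient profile of 3-year
  birth-count regressions on Pakistan DHS 2017–18 ever-married data, in
  which the structural-zero probability rises steeply with the
  respondent's age (population mean $\bar\theta \approx 0.32$);
* the two documented missingness mechanisms — husband age (default 2%
  masked, imputed back by the observed median, middle-pair mean for even
  counts) and pregnancy termination (default 64%, the share implied by
  the published observed/missing counts, imputed by the proportional
  split with the zero block first in record order, the "one" block
  absorbing the rounding remainder so totals always reconcile);
* interview dates in the 2017–18 fieldwork months, interview ages drawn
  uniformly from $[15 + w/12,\ 50)$ years so the whole window lies inside
  reproductive ages, and birth dates scattered uniformly over the window
  subject to a 9-month minimum spacing between consecutive births — a
  biological-plausibility floor, relaxed to plain sampling without
  replacement when the count makes spacing infeasible.

What it does not emulate: survey clustering, stratification and weights;
the joint dependence structure of real covariates (marginals are
independent categorical/uniform draws — any full-rank joint suffices for
testing the estimators); the all-women rescaling factor (all rates are
per ever-married woman); and real marginal distributions of PDHS 2017–18.
Passing tests therefore demonstrate the correctness of the tabulation,
likelihoods, sampler and estimator algebra — not that any particular
fitted model is adequate for real survey data.

## The bootstrap pipeline

`bootstrap_evaluate()` studies the design-based behaviour of the
model-based estimators on a fixed finite population: each replicate
draws a simple random sample *of women* without replacement (a woman's
person-year rows travel with her), fits each requested family to the
sampled rows, predicts $\hat E[y\,|\,x]$ for the non-sampled rows —
nonnegative by construction, the core advantage over linear predictors —
and forms $\hat B_g$ as observed sampled births plus predicted
non-sampled births, with $E_g$ taken from all women since exposure needs
no model.  Per measure and family the report carries the replicate mean,
the bias against the full-data direct value, and the RMSE; the RMSE
decomposes exactly into replicate variance plus squared bias.
Replicates whose fit fails or does not converge are dropped and counted.
A sample that misses a rare covariate category entirely is handled by
dropping the aliased design columns for that replicate's fit rather than
discarding the replicate.  The default of $B = 200$ replicates gives
roughly 5% Monte-Carlo error on an RMSE, adequate for the qualitative
model comparisons the pipeline is used for.  Regional tables are
produced by running the pipeline on per-region subsets.

Two properties of the estimator deserve emphasis.  *Conditional* on one
realized population, the model-based estimate shrinks each group's rate
towards the fitted regression surface, so per-group comparisons against
the realized full-data ASFRs show systematic over- and under-estimation
at extreme ages; this is intrinsic to predictive estimation, not an
implementation artefact.  Averaged over independent populations the
estimator is unbiased under a correctly specified model, which is how
the test suite frames its unbiasedness check (40 independent
populations, one sample each).  Second, when zero inflation depends on
covariates, a Poisson working model cannot represent the population mean
structure and acquires bias that inflates its RMSE; with purely constant
inflation, Poisson quasi-likelihood remains consistent for the mean and
the two working models are near-equivalent.  The zero-inflated defaults
of the generator (age-dependent inflation) are therefore the setting in
which the ZIP-based estimator's advantage is visible.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so
that every stochastic check has adequate power while the whole suite
completes in a few minutes: populations of 1,000–2,000 women (windows of
36 months), samples of half the population, $B = 200$ bootstrap
replicates, 200-replicate coverage studies at $n = 2000$, MCMC with
3 chains of 1,000 iterations, and ESS checks on AR(1) chains of length
10,000.

## Known limitations

* Exposure truncation at the age bounds can understate $E_g$ for the
  youngest and oldest groups (see above).
* The ZINB likelihood is weakly identified when the dispersion and
  inflation parts compete to explain excess zeros; count-part
  coefficients then agree with the NB fit only within statistical
  precision.
* The Bayesian module covers the Poisson model only; NB/ZIP posteriors
  are out of scope.
* Design-based machinery (Horvitz–Thompson estimation, weights,
  model-assisted estimators) is deliberately absent.
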