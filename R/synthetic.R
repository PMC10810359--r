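#' Default covariate sampling specification
#'
#' Marginal distributions used by [generate_population()] to draw the raw
#' recode covariates: independent categorical draws for the coded
#' variables and bounded uniforms for the continuous ones, with category
#' frequencies chosen to resemble an ever-married Pakistani DHS sample
#' (region shares reflecting the over-sampling of small regions, about
#' half urban, a mostly non-using contraceptive mix, husband ages 18--70,
#' marriage-to-first-birth intervals up to 10 years with a small share of
#' the DHS "no birth" code 996).
#'
#' @return Named list of distribution parameters; override elements to
#'   change a marginal.
#' @export
default_covariate_spec <- function() {
  list(
    region_probs = c(Punjab = 0.25, Sindh = 0.20, KPK = 0.20,
                     Balochistan = 0.10, GB = 0.05, ICT = 0.05,
                     AJK = 0.05, FATA = 0.10),
    urban_prob = 0.5,
    edu_probs = c(0.45, 0.15, 0.25, 0.15),          # codes 0..3
    wealth_range = c(-2, 2),                         # v191 score
    num_mem_max = 8L,                                # children ever born
    num_daughter_max = 4L,
    mtfbi_range = c(0, 120),                         # months
    mtfbi_996_prob = 0.05,                           # "no birth" code
    contraceptive_probs = c(none = 0.70, pill = 0.05, iud = 0.03,
                            injection = 0.05, female_ster = 0.06,
                            male = 0.05, withdrawal = 0.04, other = 0.02),
    preg_term_prob = 0.12,
    occupation_probs = c(not_working = 0.70, prof_tech = 0.08,
                         agriculture = 0.12, other = 0.10),
    husband_age_range = c(18, 70)
  )
}

#' Default regression coefficients for the synthetic generator
#'
#' Ground-truth coefficient vectors on the 25-column design (see
#' [design_columns()]).  The count-part defaults reproduce the coefficient
#' profile of a 3-year birth-count regression on Pakistan DHS 2017--18
#' ever-married data (Poisson profile for the `poisson`/`negbin` families,
#' the zero-inflated count profile for `zip`/`zinb`);
#' [default_inflation_coefs()] gives the matching logit-scale
#' zero-inflation profile, in which the structural-zero probability rises
#' steeply with the respondent's age.
#'
#' @param family one of `"poisson"`, `"negbin"`, `"zip"`, `"zinb"`.
#' @return Named numeric vector of length 25 (log-mean scale).
#' @export
default_count_coefs <- function(family = c("poisson", "negbin", "zip", "zinb")) {
  family <- match.arg(family)
  pois <- c(2.398, -0.094, -0.0877, -0.0142, -0.0039, -0.0879, -0.101,
            0.0519, -0.0649, 0.0731, -0.1249, 0.0211, 0.207, 0.0046,
            -0.0417, -0.2801, 0.0624, -0.5299, 0.037, -0.1376, 0.0465,
            -0.0485, 0.0923, 0.0596, -0.129)
  zipc <- c(1.756, -0.0674, -0.0499, -0.0112, -0.0352, -0.0804, -0.1754,
            0.0395, -0.0646, 0.0547, -0.0374, 0.0127, 0.1567, 0.0033,
            -0.058, -0.3399, -0.0163, -0.457, 0.0103, -0.176, 0.0623,
            -0.0193, 0.0179, 0.1091, -0.0838)
  out <- if (family %in% c("poisson", "negbin")) pois else zipc
  stats::setNames(out, design_columns())
}

#' @rdname default_count_coefs
#' @export
default_inflation_coefs <- function() {
  g <- c(-17.226, 0.4514, 0.658, 0.0652, -0.3242, 0.336, -1.7996, -0.3946,
         0.2322, -0.1968, 1.5051, -0.7039, -0.1655, -0.0166, 1.0315,
         -0.263, -1.7268, 0.8415, 0.3884, 0.0787, 1.1738, 0.4537, -1.5429,
         1.0635, 0.6009)
  stats::setNames(g, design_columns())
}

#' Configuration for the synthetic DHS-like population generator
#'
#' Bundles and validates everything [generate_population()] needs: the
#' population size, the count-model family and its ground-truth
#' parameters, the reference-window length, the covariate marginals, the
#' missingness rates the imputation rules are later asked to fill, and the
#' master seed.
#'
#' @param n_women nonnegative number of respondents.
#' @param family count-response family: `"poisson"`, `"negbin"`, `"zip"`
#'   or `"zinb"`.
#' @param window_months reference window: 12, 36 or 60 months.
#' @param count_coefs log-mean-scale coefficient vector of length 25.
#' @param inflation_coefs logit-scale zero-inflation coefficients (length
#'   25; `zip`/`zinb` only).
#' @param dispersion_r positive NB dispersion (`negbin`/`zinb` only);
#'   the Poisson is recovered as `r -> Inf`.
#' @param covariate_spec marginals, see [default_covariate_spec()].
#' @param missing_rates named fractions `husband_age` and `preg_term` in
#'   \[0, 1\].
#' @param seed integer master seed; every random stage derives its own
#'   stream from it, so regenerating with the same config is bit-identical.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_women,
                             family = c("poisson", "negbin", "zip", "zinb"),
                             window_months = 36,
                             count_coefs = default_count_coefs(family),
                             inflation_coefs = default_inflation_coefs(),
                             dispersion_r = 2,
                             covariate_spec = default_covariate_spec(),
                             missing_rates = c(husband_age = 0.02,
                                               preg_term = 0.64),
                             seed = 1L) {
  family <- match.arg(family)
  stopifnot(length(n_women) == 1L, n_women >= 0, n_women == floor(n_women))
  if (!window_months %in% c(12, 36, 60))
    stop("window_months must be 12, 36 or 60", call. = FALSE)
  p <- length(design_columns())
  if (length(count_coefs) != p)
    stop(sprintf("count_coefs must have length %d", p), call. = FALSE)
  if (family %in% c("zip", "zinb") && length(inflation_coefs) != p)
    stop(sprintf("inflation_coefs must have length %d", p), call. = FALSE)
  if (family %in% c("negbin", "zinb") &&
      (!is.finite(dispersion_r) || dispersion_r <= 0))
    stop("dispersion_r must be a positive real", call. = FALSE)
  mr <- missing_rates[c("husband_age", "preg_term")]
  if (anyNA(mr) || any(mr < 0 | mr > 1))
    stop("missing_rates must be named fractions in [0, 1]", call. = FALSE)
  structure(list(n_women = as.integer(n_women), family = family,
                 window_months = as.integer(window_months),
                 count_coefs = count_coefs,
                 inflation_coefs = inflation_coefs,
                 dispersion_r = dispersion_r,
                 covariate_spec = covariate_spec,
                 missing_rates = mr, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Draw the raw recode covariate frame (all values observed at this stage).
.sample_covariates <- function(n, spec) {
  ri <- function(p) sample.int(length(p), n, replace = TRUE, prob = p)
  data.frame(
    v024 = ri(spec$region_probs),
    v025 = ifelse(stats::runif(n) < spec$urban_prob, 1L, 2L),
    v106 = ri(spec$edu_probs) - 1L,
    v191 = stats::runif(n, spec$wealth_range[1], spec$wealth_range[2]),
    v201 = sample.int(spec$num_mem_max + 1L, n, replace = TRUE) - 1L,
    v203 = sample.int(spec$num_daughter_max + 1L, n, replace = TRUE) - 1L,
    v221 = ifelse(stats::runif(n) < spec$mtfbi_996_prob, 996L,
                  as.integer(round(stats::runif(n, spec$mtfbi_range[1],
                                                spec$mtfbi_range[2])))),
    v312 = ri(spec$contraceptive_probs) - 1L,
    v239 = ifelse(stats::runif(n) < spec$preg_term_prob, 1L, 0L),
    v717 = ri(spec$occupation_probs) - 1L,
    v730 = as.integer(round(stats::runif(n, spec$husband_age_range[1],
                                         spec$husband_age_range[2])))
  )
}

#' Generate a synthetic DHS-like population with known ground truth
#'
#' Draws `n_women` woman records: covariates from the configured
#' marginals, interview dates in the PDHS 2017--18 fieldwork months,
#' interview ages such that the whole reference window lies inside
#' reproductive ages \[15, 50), and window birth counts from the configured
#' count family with mean `mu_i = exp(x_i' beta)` (for `zip`/`zinb`, a
#' structural zero replaces the count with probability
#' `theta_i = plogis(x_i' gamma)`).  Each woman's counted births are then
#' dated inside the window by [scatter_birth_dates()].  The whole
#' procedure is deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return Object of class `fert_population`: list with `women` (raw
#'   recode data.frame including `dob_cmc`, `interview_cmc`, `birth_count`
#'   and its DHS alias `v209`/`v238`/`v208`), `births` (long data.frame
#'   `woman_id`, `birth_cmc`), the `config`, and `truth` (the generating
#'   parameters).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_women
  w <- config$window_months
  if (n == 0L) {
    women <- cbind(data.frame(woman_id = integer(0)),
                   .sample_covariates(0, config$covariate_spec),
                   data.frame(dob_cmc = integer(0), interview_cmc = integer(0),
                              birth_count = integer(0)))
    return(structure(list(women = women,
                          births = data.frame(woman_id = integer(0),
                                              birth_cmc = integer(0)),
                          config = config,
                          truth = .truth_of(config)),
                     class = "fert_population"))
  }
  women <- with_seed(derive_seed(config$seed, 1L), {
    cov <- .sample_covariates(n, config$covariate_spec)
    interview <- sample(cmc_from_date(2017, 11):cmc_from_date(2018, 4),
                        n, replace = TRUE)
    # interview-month age such that the window sits inside [15, 50) years
    age_m <- sample((.AGE_MIN_MONTHS + w):(.AGE_MAX_MONTHS - 1L),
                    n, replace = TRUE)
    cbind(data.frame(woman_id = seq_len(n)), cov,
          data.frame(dob_cmc = as.integer(interview - age_m),
                     interview_cmc = as.integer(interview)))
  })

  X <- build_design_matrix(women)
  mu <- exp(drop(X %*% config$count_coefs))
  y <- with_seed(derive_seed(config$seed, 2L), {
    base <- switch(config$family,
      poisson = stats::rpois(n, mu),
      negbin = stats::rnbinom(n, size = config$dispersion_r, mu = mu),
      zip = stats::rpois(n, mu),
      zinb = stats::rnbinom(n, size = config$dispersion_r, mu = mu))
    if (config$family %in% c("zip", "zinb")) {
      theta <- stats::plogis(drop(X %*% config$inflation_coefs))
      base[stats::runif(n) < theta] <- 0L
    }
    as.integer(base)
  })
  women$birth_count <- y
  women[[c(`12` = "v209", `36` = "v238", `60` = "v208")[as.character(w)]]] <- y

  births <- do.call(rbind, lapply(which(y > 0L), function(i) {
    data.frame(woman_id = women$woman_id[i],
               birth_cmc = scatter_birth_dates(
                 y[i], women$dob_cmc[i], women$interview_cmc[i], w,
                 seed = derive_seed(config$seed, 100L + i)))
  }))
  if (is.null(births))
    births <- data.frame(woman_id = integer(0), birth_cmc = integer(0))

  structure(list(women = women, births = births, config = config,
                 truth = .truth_of(config)),
            class = "fert_population")
}

.truth_of <- function(config) {
  list(family = config$family, count_coefs = config$count_coefs,
       inflation_coefs = if (config$family %in% c("zip", "zinb"))
         config$inflation_coefs,
       dispersion_r = if (config$family %in% c("negbin", "zinb"))
         config$dispersion_r,
       window_months = config$window_months, seed = config$seed)
}

#' @export
print.fert_population <- function(x, ...) {
  cat(sprintf("Synthetic DHS-like population: %d women, %s counts, %d-month window\n",
              nrow(x$women), x$config$family, x$config$window_months))
  cat(sprintf("  total births in window: %d\n", sum(x$women$birth_count)))
  invisible(x)
}

#' Date a woman's window births at month resolution
#'
#' Draws `birth_count` birth months uniformly without replacement from the
#' months of the reference window in which the mother is of reproductive
#' age, subject to at least 9 months between consecutive births whenever
#' that many spaced months exist; when the spacing constraint is
#' infeasible it is relaxed to plain sampling without replacement.
#'
#' @param birth_count nonnegative number of births to place.
#' @param dob_cmc,interview_cmc,window_months as in [woman_exposure()].
#' @param seed optional integer seed (same seed, same dates).
#' @return Sorted integer vector of `birth_count` CMCs.
#' @export
scatter_birth_dates <- function(birth_count, dob_cmc, interview_cmc,
                                window_months, seed = NULL) {
  stop_if_not_count(birth_count, "birth_count")
  if (birth_count == 0L) return(integer(0))
  months <- (interview_cmc - window_months + 1L):interview_cmc
  age <- .age_in_month(months, dob_cmc)
  months <- months[age >= .AGE_MIN_MONTHS & age < .AGE_MAX_MONTHS]
  m <- length(months)
  if (birth_count > m)
    stop("birth_count exceeds the feasible months in the window",
         call. = FALSE)
  gap <- 9L
  with_seed(seed, {
    if ((birth_count - 1L) * gap + birth_count <= m) {
      # uniform over spaced subsets: sample positions in the contracted
      # window, then re-expand by the 9-month gaps
      pos <- sort(sample.int(m - (birth_count - 1L) * gap, birth_count))
      idx <- pos + (seq_len(birth_count) - 1L) * gap
    } else {
      idx <- sort(sample.int(m, birth_count))
    }
    as.integer(months[idx])
  })
}

#' Mask values to emulate survey missingness
#'
#' Independently masks each woman's husband age (`v730` set to `NA`) and
#' pregnancy-termination response (`v239` set to the DHS missing code 9)
#' with the configured rates, creating the holes that
#' [impute_husband_age()] and [impute_preg_term()] later fill.
#'
#' @param women woman-records data.frame.
#' @param missing_rates named fractions `husband_age`, `preg_term`.
#' @param seed optional integer seed.
#' @return The records with masked values.
#' @export
inject_missingness <- function(women, missing_rates = c(husband_age = 0.02,
                                                        preg_term = 0.64),
                               seed = NULL) {
  r <- missing_rates
  if (anyNA(r[c("husband_age", "preg_term")]) || any(r < 0 | r > 1))
    stop("missing_rates must be named fractions in [0, 1]", call. = FALSE)
  n <- nrow(women)
  with_seed(seed, {
    women$v730[stats::runif(n) < r[["husband_age"]]] <- NA
    women$v239[stats::runif(n) < r[["preg_term"]]] <- 9L
  })
  women
}

#' Write a synthetic population to disk
#'
#' Emits `women.csv` (raw recode columns plus CMC dates and the window
#' birth count), `births.csv` (`woman_id`, `birth_cmc`) and
#' `truth.json` (the generating parameters) into `dir`.
#'
#' @param population a `fert_population`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "fert_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("women.csv", "births.csv", "truth.json"))
  utils::write.csv(population$women, paths[1], row.names = FALSE, na = "")
  utils::write.csv(population$births, paths[2], row.names = FALSE)
  jsonlite::write_json(population$truth, paths[3], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
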