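# The model-based predictive estimation pipeline: draw a simple random
# sample of women, fit a count model to the sampled person-year rows,
# predict births for the non-sampled rows, and evaluate the resulting
# fertility measures against the full-data direct estimates by bootstrap.

.MEASURES <- c(paste0("asfr_", age_group_labels()), "tfr", "gfr", "grr")

#' Bootstrap sampling plan
#'
#' @param n sample size (women drawn per replicate, without replacement).
#' @param B number of bootstrap replicates.
#' @param families model families fitted in each replicate (subset of
#'   `"poisson"`, `"negbin"`, `"zip"`, `"zinb"`).
#' @param window_months reference window length.
#' @param seed master seed; replicate b derives its own stream.
#' @return Object of class `sampling_plan`.
#' @export
sampling_plan <- function(n, B = 200L, families = c("poisson", "zip"),
                          window_months = 36L, seed = 1L) {
  families <- match.arg(families, .FAMILIES, several.ok = TRUE)
  stopifnot(n > 0, B >= 1)
  structure(list(n = as.integer(n), B = as.integer(B), families = families,
                 window_months = as.integer(window_months),
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

#' Partition a population into sampled and non-sampled women
#'
#' Simple random sampling without replacement of `n` women; the two id
#' sets are disjoint and their union is the population.
#'
#' @param records a `fert_population`, a data.frame with a `woman_id`
#'   column, or a vector of woman ids.
#' @param n sample size (`<= N`).
#' @param seed optional integer seed.
#' @return List with `sampled` and `non_sampled` id vectors.
#' @export
draw_sample <- function(records, n, seed = NULL) {
  ids <- if (inherits(records, "fert_population")) records$women$woman_id
         else if (is.data.frame(records)) unique(records$woman_id)
         else records
  N <- length(ids)
  if (n > N) stop("n exceeds the population size", call. = FALSE)
  s <- with_seed(seed, sample(ids, n))
  list(sampled = s, non_sampled = setdiff(ids, s))
}

#' Model-based (predictive) fertility estimates from a sample
#'
#' Fits the chosen count family to the sampled women's person-year rows
#' (births as response, log woman-years as offset), predicts the expected
#' births `E[y|x]` for every non-sampled row, and forms group totals
#' `B_g = sum(observed sampled births) + sum(predicted non-sampled
#' births)`.  Exposure needs no model, so `E_g` comes from all women.
#' The fertility measures are then computed exactly as for full data;
#' with the whole population sampled the result equals the direct
#' estimates.
#'
#' @param person_years person-year table from [build_person_year_table()]
#'   covering the whole population.
#' @param sampled_ids woman ids of the sampled part.
#' @param family count-model family.
#' @param p_female female-birth proportion(s) for the GRR.
#' @return A `fert_estimates` object; the fitted model is attached as
#'   attribute `"fit"`.
#' @export
model_based_estimate <- function(person_years, sampled_ids,
                                 family = "poisson", p_female = 0.5) {
  family <- match.arg(family, .FAMILIES)
  pyt <- person_years
  in_s <- pyt$woman_id %in% sampled_ids
  cols <- design_columns()
  Xs <- as.matrix(pyt[in_s, cols, drop = FALSE])
  # a sample can miss a rare category entirely; drop the aliased columns
  # for this fit rather than refusing the replicate
  q <- qr(Xs)
  keep <- sort(q$pivot[seq_len(q$rank)])
  fit <- fit_count_model(family, Xs[, keep, drop = FALSE], pyt$births[in_s],
                         offset = log(pyt$exposure_years[in_s]))
  yhat <- numeric(nrow(pyt))
  yhat[in_s] <- pyt$births[in_s]
  if (any(!in_s)) {
    Xr <- as.matrix(pyt[!in_s, cols, drop = FALSE])[, keep, drop = FALSE]
    yhat[!in_s] <- predict(fit, Xr, offset = log(pyt$exposure_years[!in_s]))
  }
  f <- factor(pyt$g, levels = 0:6)
  B <- as.numeric(tapply(yhat, f, sum, default = 0))
  E <- as.numeric(tapply(pyt$exposure_years, f, sum, default = 0))
  out <- fertility_estimates(B, E, p_female)
  attr(out, "fit") <- fit
  out
}

.estimates_vector <- function(est) {
  stats::setNames(c(est$asfr, est$tfr, est$gfr, est$grr), .MEASURES)
}

#' Bootstrap evaluation of the model-based estimators
#'
#' The headline procedure: for each of `plan$B` replicates, draw a simple
#' random sample of `plan$n` women, compute the model-based fertility
#' estimates under every requested family, and compare them with the
#' direct full-data estimates.  For each (family, measure) pair the
#' report carries the mean estimate, the bias (mean - full-data value)
#' and the RMSE `sqrt(mean((estimate_b - full)^2))`.  Replicates whose
#' fit fails or does not converge are dropped and counted, never imputed.
#'
#' @param population a `fert_population`, or a person-year table from
#'   [build_person_year_table()].
#' @param plan a [sampling_plan()].
#' @param p_female female-birth proportion(s) for the GRR.
#' @param verbose print per-replicate progress to stderr.
#' @return Object of class `fert_bootstrap`: list with `summary`
#'   (data.frame family x measure with mean/bias/rmse), `reference` (the
#'   full-data `fert_estimates`), `replicates` (B x family x measure
#'   array, `NA` for failed fits) and `n_failed` per family.
#' @export
bootstrap_evaluate <- function(population, plan, p_female = 0.5,
                               verbose = FALSE) {
  stopifnot(inherits(plan, "sampling_plan"))
  pyt <- if (inherits(population, "fert_population"))
    build_person_year_table(population) else population
  ids <- unique(pyt$woman_id)
  if (plan$n > length(ids))
    stop("plan$n exceeds the number of women with exposure", call. = FALSE)

  agg <- aggregate_exposure(pyt)
  reference <- fertility_estimates(agg$B, agg$E, p_female)
  ref_vec <- .estimates_vector(reference)

  reps <- array(NA_real_,
                dim = c(plan$B, length(plan$families), length(.MEASURES)),
                dimnames = list(NULL, plan$families, .MEASURES))
  for (b in seq_len(plan$B)) {
    part <- draw_sample(ids, plan$n, seed = derive_seed(plan$seed, b))
    for (fam in plan$families) {
      est <- tryCatch({
        e <- model_based_estimate(pyt, part$sampled, fam, p_female)
        if (!attr(e, "fit")$converged) NULL else e
      }, error = function(e) NULL)
      if (!is.null(est)) reps[b, fam, ] <- .estimates_vector(est)
    }
    if (verbose)
      message(sprintf("replicate %d/%d done", b, plan$B))
  }
  n_failed <- vapply(plan$families,
                     function(fam) sum(is.na(reps[, fam, 1])), integer(1))
  if (any(n_failed == plan$B))
    stop("all replicates failed for family: ",
         paste(plan$families[n_failed == plan$B], collapse = ", "),
         call. = FALSE)
  summ <- do.call(rbind, lapply(plan$families, function(fam) {
    m <- reps[, fam, , drop = FALSE][, 1, ]
    m <- matrix(m, ncol = length(.MEASURES),
                dimnames = list(NULL, .MEASURES))
    ok <- !is.na(m[, 1])
    dev <- sweep(m[ok, , drop = FALSE], 2, ref_vec)
    data.frame(family = fam, measure = .MEASURES,
               mean = colMeans(m[ok, , drop = FALSE]),
               bias = colMeans(dev),
               rmse = sqrt(colMeans(dev^2)),
               reference = unname(ref_vec), row.names = NULL)
  }))
  structure(list(summary = summ, reference = reference, replicates = reps,
                 n_failed = n_failed, plan = plan),
            class = "fert_bootstrap")
}

#' @export
print.fert_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap evaluation: B = %d replicates, n = %d women per sample\n",
              x$plan$B, x$plan$n))
  if (any(x$n_failed > 0))
    cat("  failed replicates:",
        paste(sprintf("%s=%d", names(x$n_failed), x$n_failed),
              collapse = ", "), "\n")
  print(report_tables(x))
  invisible(x)
}

#' Estimate (RMSE) report in the familiar table layout
#'
#' One row per measure: the mean bootstrap estimate with its RMSE for
#' every family, the family with the smallest RMSE flagged `best`, plus
#' the full-data reference column.
#'
#' @param result a `fert_bootstrap`.
#' @return data.frame with columns `measure`, one `<family>` column of
#'   `"estimate (RMSE)"` strings per family, `best` (the minimum-RMSE
#'   family) and `full_data`.  The numeric long-format table is attached
#'   as attribute `"long"` for programmatic use.
#' @export
report_tables <- function(result) {
  stopifnot(inherits(result, "fert_bootstrap"))
  s <- result$summary
  fams <- unique(s$family)
  out <- data.frame(measure = .MEASURES)
  for (fam in fams) {
    sf <- s[s$family == fam, ]
    out[[fam]] <- sprintf("%.2f (%.2f)",
                          sf$mean[match(.MEASURES, sf$measure)],
                          sf$rmse[match(.MEASURES, sf$measure)])
  }
  out$best <- vapply(.MEASURES, function(ms) {
    sm <- s[s$measure == ms, ]
    sm$family[which.min(sm$rmse)]
  }, character(1))
  out$full_data <- s$reference[match(.MEASURES, s$measure)]
  rownames(out) <- NULL
  attr(out, "long") <- s
  out
}
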