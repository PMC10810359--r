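# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's stream.  A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct 31-bit sub-seed from a master seed and a stream label,
# so independent stages (covariates, counts, birth dates, masking, bootstrap
# replicates) get reproducible, non-overlapping seeds.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  x <- (as.double(seed) * 69069 + 12345 * as.double(stream)) %% 2147483629
  as.integer(x) + 1L
}

stop_if_not_count <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x)))
    stop(sprintf("'%s' must contain nonnegative integers", name), call. = FALSE)
  invisible(TRUE)
}
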