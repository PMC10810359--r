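#' Design-matrix column layout
#'
#' The fixed predictor set used throughout the package: an intercept plus
#' 24 socio-demographic and family-planning covariates coded from the DHS
#' women's-recode variables.  Region is recoded to five dummies with Punjab
#' (together with Gilgit-Baltistan and Azad Jammu & Kashmir, which carry no
#' dummy) as the base, contraceptive method to seven dummies with "not
#' using" as the base, and occupation to three dummies with "not working"
#' as the base.
#'
#' @return Character vector of the 25 column names, in fitting order.
#' @export
design_columns <- function() {
  c("Intercept", "Res_age", "Residence", "Age_husbnd",
    "Sindh", "KPK", "Balochistan", "ICT", "FATA",
    "Edu", "WI", "Num_mem", "Num_daughter", "MTFBI",
    "Cont_Pill", "IUD", "Cont_Inj", "Cont_female", "Cont_male",
    "Cont_withdrawal", "Cont_other", "Preg_term_new",
    "Prof_tech", "Prof_Agr", "Prof_other")
}

# Canonical raw recode columns a woman-level file must provide.
.RECODE_COLS <- c("woman_id", "dob_cmc", "interview_cmc", "v024", "v025",
                  "v106", "v191", "v201", "v203", "v221", "v312", "v239",
                  "v717", "v730")

#' Read a woman-level recode CSV
#'
#' Reads a comma-separated, UTF-8 woman-level file with a mandatory header
#' row.  An optional schema maps external column names onto the canonical
#' recode names (`woman_id`, `dob_cmc`, `interview_cmc`, `v024`, `v025`,
#' `v106`, `v191`, `v201`, `v203`, `v221`, `v312`, `v239`, `v717`, `v730`,
#' plus any of the window birth counts `v209`/`v238`/`v208`).  Blank
#' husband-age (`v730`) cells become `NA` (missing, to be imputed);
#' non-integer CMC dates are a hard error reporting the offending row
#' numbers.
#'
#' @param path file path.
#' @param schema optional mapping: a named character vector
#'   (`c(external = "canonical")`) or the path of a two-column CSV with
#'   columns `external`, `canonical`.
#' @return data.frame of woman records with canonical column names.
#' @export
read_recode_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    if (is.character(schema) && is.null(names(schema)) && length(schema) == 1L) {
      m <- utils::read.csv(schema, stringsAsFactors = FALSE)
      schema <- stats::setNames(m$canonical, m$external)
    }
    hit <- names(df) %in% names(schema)
    names(df)[hit] <- unname(schema[names(df)[hit]])
  }
  missing_cols <- setdiff(.RECODE_COLS, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c("dob_cmc", "interview_cmc")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad))
      stop(sprintf("non-integer %s in row(s): %s", col,
                   paste(utils::head(bad, 10L), collapse = ", ")),
           call. = FALSE)
    df[[col]] <- as.integer(v)
  }
  df$v730 <- suppressWarnings(as.numeric(df$v730))  # blank -> NA (missing)
  df
}

#' Impute missing husband age by the observed median
#'
#' Replaces missing husband/partner ages (`v730`) with the median of the
#' observed ages; observed values are untouched.  With an even number of
#' observed values the median is the mean of the middle pair.
#'
#' @param records data.frame with a `v730` column.
#' @return The records with `v730` complete.
#' @export
impute_husband_age <- function(records) {
  miss <- is.na(records$v730)
  if (all(miss)) stop("all husband ages are missing", call. = FALSE)
  if (any(miss))
    records$v730[miss] <- stats::median(records$v730[!miss])
  records
}

#' Proportional split of missing pregnancy-termination responses
#'
#' Divides `n_total` missing yes/no responses between the two levels in
#' proportion to the observed counts: the "no" share is
#' `round(n_observed_zero * n_total / (n_observed_zero + n_observed_one))`
#' (half away from zero) and the "yes" share is the complement, so the two
#' parts always reconcile to `n_total`.
#'
#' @param n_observed_zero,n_observed_one observed counts of 0s and 1s.
#' @param n_total number of missing responses to allocate.
#' @return Integer vector `c(n_assign_zero, n_assign_one)`.
#' @examples
#' split_preg_term_missing(4676, 13317, 50495)  # 13123, 37372
#' @export
split_preg_term_missing <- function(n_observed_zero, n_observed_one, n_total) {
  stop_if_not_count(c(n_observed_zero, n_observed_one, n_total), "counts")
  if (n_observed_zero + n_observed_one == 0)
    stop("both observed counts are zero", call. = FALSE)
  share <- n_observed_zero * n_total / (n_observed_zero + n_observed_one)
  n_zero <- as.integer(floor(share + 0.5))  # round half away from zero
  c(n_zero, as.integer(n_total) - n_zero)
}

#' Impute missing pregnancy-termination indicators
#'
#' Applies [split_preg_term_missing()] to the records whose `v239` is coded
#' 9 (missing): in record order, the first block receives 0 and the
#' remainder 1.
#'
#' @param records data.frame with a `v239` column coded 0/1/9.
#' @return Records with `v239` in \{0, 1\}.
#' @export
impute_preg_term <- function(records) {
  miss <- which(records$v239 == 9)
  if (!length(miss)) return(records)
  n0 <- sum(records$v239 == 0)
  n1 <- sum(records$v239 == 1)
  parts <- split_preg_term_missing(n0, n1, length(miss))
  records$v239[miss] <- rep(c(0L, 1L), parts)
  records
}

.check_codes <- function(x, valid, name) {
  bad <- !(x %in% valid)
  if (any(bad))
    stop(sprintf("unknown %s code(s): %s", name,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
}

#' Build the Table-style design matrix from woman records
#'
#' Codes the raw recode variables into the fixed 25-column predictor matrix
#' (see [design_columns()]): respondent age in completed years derived from
#' the CMC dates; urban-residence, region, contraceptive-method and
#' occupation dummies; the wealth-index dummy (`1` iff the wealth score
#' `v191 > 0`); counts of children/daughters; marriage-to-first-birth
#' interval with the DHS "no birth" code 996 and negative intervals set to
#' 0; and the (imputed) pregnancy-termination indicator.  Unknown category
#' codes are hard errors.  If the input already carries all design columns
#' (an already-coded numeric table) it is returned as a matrix unchanged,
#' so the coding step is idempotent.
#'
#' @param records data.frame of imputed woman records (no missing `v730`,
#'   no `v239 == 9`), or an already-coded table.
#' @return Numeric matrix with `nrow(records)` rows and the 25 design
#'   columns.
#' @export
build_design_matrix <- function(records) {
  cols <- design_columns()
  if (all(cols %in% names(records)))
    return(as.matrix(records[cols]))
  need <- setdiff(.RECODE_COLS, names(records))
  if (length(need))
    stop("records lack column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyNA(records$v730))
    stop("v730 has missing values; run impute_husband_age() first",
         call. = FALSE)
  if (any(records$v239 == 9))
    stop("v239 has missing codes (9); run impute_preg_term() first",
         call. = FALSE)
  .check_codes(records$v024, 1:8, "region (v024)")
  .check_codes(records$v025, 1:2, "residence (v025)")
  .check_codes(records$v106, 0:3, "education (v106)")
  .check_codes(records$v312, 0:7, "contraceptive method (v312)")
  .check_codes(records$v239, 0:1, "pregnancy termination (v239)")
  .check_codes(records$v717, 0:3, "occupation (v717)")

  n <- nrow(records)
  X <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  X[, "Intercept"] <- 1
  X[, "Res_age"] <- (records$interview_cmc - records$dob_cmc) %/% 12L
  X[, "Residence"] <- as.numeric(records$v025 == 1)
  X[, "Age_husbnd"] <- records$v730
  X[, "Sindh"] <- as.numeric(records$v024 == 2)
  X[, "KPK"] <- as.numeric(records$v024 == 3)
  X[, "Balochistan"] <- as.numeric(records$v024 == 4)
  X[, "ICT"] <- as.numeric(records$v024 == 6)
  X[, "FATA"] <- as.numeric(records$v024 == 8)
  X[, "Edu"] <- records$v106
  X[, "WI"] <- as.numeric(records$v191 > 0)
  X[, "Num_mem"] <- records$v201
  X[, "Num_daughter"] <- records$v203
  X[, "MTFBI"] <- ifelse(records$v221 == 996 | records$v221 < 0, 0,
                         records$v221)
  X[, "Cont_Pill"] <- as.numeric(records$v312 == 1)
  X[, "IUD"] <- as.numeric(records$v312 == 2)
  X[, "Cont_Inj"] <- as.numeric(records$v312 == 3)
  X[, "Cont_female"] <- as.numeric(records$v312 == 4)
  X[, "Cont_male"] <- as.numeric(records$v312 == 5)
  X[, "Cont_withdrawal"] <- as.numeric(records$v312 == 6)
  X[, "Cont_other"] <- as.numeric(records$v312 == 7)
  X[, "Preg_term_new"] <- records$v239
  X[, "Prof_tech"] <- as.numeric(records$v717 == 1)
  X[, "Prof_Agr"] <- as.numeric(records$v717 == 2)
  X[, "Prof_other"] <- as.numeric(records$v717 == 3)
  X
}
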