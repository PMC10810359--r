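test_that("synthetic populations round-trip through the CSV interface", {
  cfg <- synthetic_config(50, family = "poisson", seed = 3)
  pop <- generate_population(cfg)
  pop$women <- inject_missingness(pop$women,
                                  c(husband_age = 0.2, preg_term = 0.3),
                                  seed = 9)
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  got <- read_recode_csv(file.path(dir, "women.csv"))
  for (col in c("woman_id", "dob_cmc", "interview_cmc", "v024", "v106",
                "v221", "v312", "v239", "v730", "birth_count"))
    expect_equal(got[[col]], pop$women[[col]])
  expect_equal(got$v191, pop$women$v191, tolerance = 1e-12)
})

test_that("empty and malformed recode files are handled explicitly", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(3, family = "poisson", seed = 1)
  pop <- generate_population(cfg)
  write_population(pop, dir)
  # empty file with header -> empty collection
  w <- utils::read.csv(file.path(dir, "women.csv"))
  utils::write.csv(w[0, ], file.path(dir, "empty.csv"), row.names = FALSE)
  expect_equal(nrow(read_recode_csv(file.path(dir, "empty.csv"))), 0L)
  # missing required column
  utils::write.csv(w[setdiff(names(w), "v024")], file.path(dir, "bad.csv"),
                   row.names = FALSE)
  expect_error(read_recode_csv(file.path(dir, "bad.csv")), "v024")
  # non-integer CMC reported with its row number
  w2 <- w; w2$dob_cmc[2] <- "not-a-date"
  utils::write.csv(w2, file.path(dir, "bad2.csv"), row.names = FALSE)
  expect_error(read_recode_csv(file.path(dir, "bad2.csv")), "row.*2")
  # blank husband age becomes a missing value
  w3 <- w; w3$v730[1] <- NA
  utils::write.csv(w3, file.path(dir, "miss.csv"), row.names = FALSE, na = "")
  expect_true(is.na(read_recode_csv(file.path(dir, "miss.csv"))$v730[1]))
})

test_that("schema files map external column names onto recode names", {
  dir <- withr::local_tempdir()
  pop <- generate_population(synthetic_config(5, family = "poisson", seed = 2))
  w <- pop$women
  names(w)[names(w) == "v024"] <- "region_code"
  utils::write.csv(w, file.path(dir, "ext.csv"), row.names = FALSE)
  utils::write.csv(data.frame(external = "region_code", canonical = "v024"),
                   file.path(dir, "schema.csv"), row.names = FALSE)
  got <- read_recode_csv(file.path(dir, "ext.csv"),
                         schema = file.path(dir, "schema.csv"))
  expect_equal(got$v024, pop$women$v024)
  got2 <- read_recode_csv(file.path(dir, "ext.csv"),
                          schema = c(region_code = "v024"))
  expect_equal(got2$v024, pop$women$v024)
})

test_that("husband age is imputed by the observed median", {
  rec <- data.frame(v730 = c(20, 25, 40, NA))
  expect_equal(impute_husband_age(rec)$v730, c(20, 25, 40, 25))
  # even count: mean of the middle pair
  rec <- data.frame(v730 = c(20, 30, NA))
  expect_equal(impute_husband_age(rec)$v730, c(20, 30, 25))
  rec <- data.frame(v730 = c(31, 35))
  expect_identical(impute_husband_age(rec), rec)
  expect_error(impute_husband_age(data.frame(v730 = c(NA_real_, NA_real_))),
               "all")
})

test_that("missing pregnancy-termination responses split proportionally", {
  expect_equal(split_preg_term_missing(4676, 13317, 50495), c(13123L, 37372L))
  expect_equal(split_preg_term_missing(1, 1, 8), c(4L, 4L))
  expect_equal(split_preg_term_missing(1, 3, 8), c(2L, 6L))
  expect_equal(sum(split_preg_term_missing(7, 13, 101)), 101L)
  expect_error(split_preg_term_missing(0, 0, 5), "zero")
  expect_error(split_preg_term_missing(-1, 3, 5), "nonnegative")
})

test_that("imputed pregnancy terminations fill zeros first in record order", {
  rec <- data.frame(v239 = c(9L, 0L, 9L, 1L, 9L, 9L, 1L, 1L))
  out <- impute_preg_term(rec)
  # observed 1 zero, 3 ones; 4 missing -> 1 zero then 3 ones, in order
  expect_equal(out$v239[c(1, 3, 5, 6)], c(0L, 1L, 1L, 1L))
  expect_equal(out$v239[c(2, 4, 7, 8)], rec$v239[c(2, 4, 7, 8)])
  expect_identical(impute_preg_term(data.frame(v239 = c(0L, 1L)))$v239,
                   c(0L, 1L))
})

test_that("design matrix applies the documented dummy codings", {
  rec <- data.frame(woman_id = 1:3, dob_cmc = c(1000, 1000, 1000),
                    interview_cmc = c(1360, 1400, 1417),
                    v024 = c(1L, 3L, 5L), v025 = c(2L, 1L, 1L),
                    v106 = c(0L, 2L, 3L), v191 = c(-0.3, 0.8, 0),
                    v201 = c(2L, 4L, 0L), v203 = c(1L, 2L, 0L),
                    v221 = c(996L, 24L, -5L), v312 = c(0L, 5L, 2L),
                    v239 = c(0L, 1L, 0L), v717 = c(0L, 2L, 1L),
                    v730 = c(30, 45, 50))
  X <- build_design_matrix(rec)
  expect_identical(colnames(X), design_columns())
  expect_equal(ncol(X), 25L)
  expect_equal(nrow(X), 3L)
  expect_true(all(X[, "Intercept"] == 1))
  # base categories: Punjab, rural, no contraception, not working
  expect_true(all(X[1, c("Sindh", "KPK", "Balochistan", "ICT", "FATA",
                         "Residence", "Cont_Pill", "IUD", "Cont_Inj",
                         "Cont_female", "Cont_male", "Cont_withdrawal",
                         "Cont_other", "Prof_tech", "Prof_Agr",
                         "Prof_other")] == 0))
  # GB (code 5) also maps to no region dummy
  expect_true(all(X[3, c("Sindh", "KPK", "Balochistan", "ICT", "FATA")] == 0))
  expect_equal(unname(X[2, "KPK"]), 1)
  # negative wealth score -> WI = 0; positive -> 1
  expect_equal(unname(X[, "WI"]), c(0, 1, 0))
  # MTFBI code 996 and negative intervals -> 0
  expect_equal(unname(X[, "MTFBI"]), c(0, 24, 0))
  # respondent age in completed years from the CMC dates
  expect_equal(unname(X[, "Res_age"]), c(30, 33, 34))
  expect_equal(unname(X[2, c("Cont_male", "Prof_Agr")]), c(1, 1))
  expect_equal(unname(X[3, "IUD"]), 1)
})

test_that("design-matrix construction is idempotent and strict", {
  pop <- generate_population(synthetic_config(20, family = "poisson",
                                              seed = 4))
  X <- build_design_matrix(pop$women)
  X2 <- build_design_matrix(as.data.frame(X))
  expect_equal(X2, X)
  # unknown category codes are hard errors, not silent base assignment
  bad <- pop$women; bad$v312[1] <- 11L
  expect_error(build_design_matrix(bad), "contraceptive")
  bad <- pop$women; bad$v024[1] <- 9L
  expect_error(build_design_matrix(bad), "region")
  # unimputed records are refused
  bad <- pop$women; bad$v730[1] <- NA
  expect_error(build_design_matrix(bad), "impute_husband_age")
  bad <- pop$women; bad$v239[1] <- 9L
  expect_error(build_design_matrix(bad), "impute_preg_term")
})
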