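make_record <- function(...) {
  vals <- list(...)
  cb <- load_codebook()
  data <- as.data.frame(lapply(vals, as.integer))
  vtdisparity:::as_cohort(data, cb, "record")
}

test_that("the nine built-in contrasts encode their focal groups", {
  cs <- builtin_contrasts()
  expect_length(cs, 9)
  expect_setequal(names(cs),
                  c("white_non_hispanic", "wage_income", "no_cooccurring_disorder",
                    "male", "no_insurance", "veteran", "age_under_35",
                    "alcohol_primary", "opioid_primary"))
  # white non-Hispanic requires both clauses of the conjunction
  expect_equal(derive_indicator(make_record(RACE = 5, ETHNIC = 4),
                                cs$white_non_hispanic), 1L)
  expect_equal(derive_indicator(make_record(RACE = 5, ETHNIC = 2),
                                cs$white_non_hispanic), 0L)
  expect_equal(derive_indicator(make_record(PSYPROB = 2),
                                cs$no_cooccurring_disorder), 1L)
  expect_equal(derive_indicator(make_record(VET = 1), cs$veteran), 1L)
  # 25-29 is an under-35 age bin
  expect_equal(derive_indicator(make_record(AGE = 5), cs$age_under_35), 1L)
  expect_equal(derive_indicator(make_record(AGE = 7), cs$age_under_35), 0L)
  # opioid = heroin, non-prescription methadone, other opiates/synthetics
  expect_equal(derive_indicator(make_record(SUB1 = 6), cs$opioid_primary), 1L)
  expect_equal(derive_indicator(make_record(SUB1 = 2), cs$opioid_primary), 0L)
})

test_that("missing source variables propagate to a missing indicator", {
  cs <- builtin_contrasts()
  expect_true(is.na(derive_indicator(make_record(PRIMINC = NA), cs$wage_income)))
  expect_true(is.na(derive_indicator(make_record(RACE = NA, ETHNIC = 4),
                                     cs$white_non_hispanic)))
  expect_error(derive_indicator(random_toy_cohort(5), cs$veteran), "absent")
})

test_that("indicators are pure per-record functions (permutation equivariance)", {
  cfg <- synthetic_config(n = 300, variables = c("RACE", "ETHNIC", "GENDER"))
  s <- sample_cohort(cfg, seed = 2)
  ct <- builtin_contrasts()$white_non_hispanic
  ind <- derive_indicator(s$cohort, ct)
  expect_true(all(ind %in% c(0L, 1L)))  # fully observed: never missing
  perm <- sample(300)
  permuted <- s$cohort
  permuted$data <- s$cohort$data[perm, , drop = FALSE]
  expect_equal(derive_indicator(permuted, ct), ind[perm])
})

test_that("one-hot designs have complete blocks that sum to one", {
  ch <- toy_cohort(data.frame(REASON = c(1L, 2L), COLOR = c(1L, NA), SIZE = c(2L, 1L)))
  d <- build_design(ch)
  # k categories + 1 missing indicator per variable; REASON excluded
  expect_equal(ncol(d$x), (3 + 1) + (2 + 1))
  for (vn in names(d$variables)) {
    block <- d$x[, d$variables[[vn]]$columns, drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, 2))
  }
  expect_equal(d$x[2, "COLOR=missing"], c(`COLOR=missing` = 1))
})

test_that("stage one carries T and hides sources; stage two masks everything", {
  cfg <- synthetic_config(n = 60, variables = c("RACE", "ETHNIC", "GENDER", "LOS"))
  s <- sample_cohort(cfg, seed = 3)
  ct <- builtin_contrasts()$white_non_hispanic
  d1 <- build_design(s$cohort, ct, "one")
  expect_true("white_non_hispanic" %in% colnames(d1$x))
  expect_false(any(grepl("^RACE=|^ETHNIC=", colnames(d1$x))))
  d1s <- build_design(s$cohort, ct, "one", include_sources_stage_one = TRUE)
  expect_true(any(grepl("^RACE=", colnames(d1s$x))))
  d2 <- build_design(s$cohort, ct, "two")
  expect_false("white_non_hispanic" %in% colnames(d2$x))
  expect_false(any(grepl("^RACE=|^ETHNIC=", colnames(d2$x))))
  expect_false(any(grepl("^REASON=", colnames(d2$x))))
})

test_that("records with a missing indicator are dropped and counted", {
  ch <- toy_cohort(data.frame(REASON = rep(1L, 4), COLOR = c(1L, NA, 3L, NA),
                              SIZE = rep(1L, 4)))
  ct <- disparity_contrast("red", list(COLOR = 1L))
  d1 <- build_design(ch, ct, "one")
  expect_equal(d1$n_dropped, 2L)
  expect_equal(d1$rows, c(1L, 3L))
  expect_equal(unname(d1$x[, "red"]), c(1, 0))
})
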