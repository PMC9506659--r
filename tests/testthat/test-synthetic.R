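test_that("a fully null model yields a balanced outcome and zero truth", {
  cfg <- synthetic_config(n = 10000, variables = c("GENDER", "SUB2"), beta0 = 0)
  s <- sample_cohort(cfg, seed = 5)
  rate <- mean(code_outcome(s$cohort))
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(rate - 0.5), 3 * se)
  expect_equal(s$truth$z_true, rep(0, 10000))
})

test_that("true twin differences follow the logistic closed form", {
  cb <- load_codebook()
  pred <- list(SERVICES = c(6L, 7L))
  cfg <- synthetic_config(n = 100, variables = c("SERVICES", "GENDER"),
                          beta0 = -0.5, beta_T = 0,
                          interactions = list(list(predicate = pred, gamma = 0.8)))
  rows <- data.frame(SERVICES = c(6L, 7L, 2L), GENDER = c(1L, 2L, 1L))
  z <- true_twin_difference(rows, cfg)
  expect_equal(z[1:2], rep(sigmoid(0.3) - sigmoid(-0.5), 2))
  expect_equal(z[3], 0)
  # a huge main effect saturates at sigma(10) - 0.5
  cfg2 <- synthetic_config(n = 10, variables = "GENDER", beta0 = 0, beta_T = 10)
  expect_equal(true_twin_difference(data.frame(GENDER = 1L), cfg2),
               sigmoid(10) - 0.5)
})

test_that("expected subgroup difference matches independent enumeration", {
  # two active binary-ish variables; verify against a hand enumeration
  marg <- list(GENDER = c(`1` = 0.6, `2` = 0.4),
               NOPRIOR = c(`1` = 0.3, `2` = 0.7))
  cfg <- synthetic_config(n = 10, variables = c("GENDER", "NOPRIOR"),
                          marginals = marg, beta0 = -0.5,
                          beta_x = list(GENDER = c(`1` = 0.2)),
                          interactions = list(list(predicate = list(NOPRIOR = 1L),
                                                   gamma = 0.7)))
  # oracle: enumerate the four cells directly
  cells <- expand.grid(GENDER = 1:2, NOPRIOR = 1:2)
  w <- marg$GENDER[as.character(cells$GENDER)] * marg$NOPRIOR[as.character(cells$NOPRIOR)]
  eta0 <- -0.5 + ifelse(cells$GENDER == 1, 0.2, 0)
  z <- ifelse(cells$NOPRIOR == 1, sigmoid(eta0 + 0.7) - sigmoid(eta0), 0)
  inS <- cells$NOPRIOR == 1
  oracle <- sum(w[inS] * z[inS]) / sum(w[inS])
  expect_equal(expected_subgroup_z(cfg, list(NOPRIOR = 1L)), oracle, tolerance = 1e-12)
  # and the population mean with no predicate
  expect_equal(expected_subgroup_z(cfg), sum(w * z), tolerance = 1e-12)
})

test_that("sampled truth means agree with the exact subgroup expectation", {
  cfg <- synthetic_scenario("planted", n = 50000)
  s <- sample_cohort(cfg, seed = 21)
  pred <- attr(cfg, "predicate")
  inS <- s$cohort$data$FREQ1_D %in% pred$FREQ1_D
  expect_lt(abs(mean(s$truth$z_true[inS]) - attr(cfg, "truth_delta")), 0.002)
  expect_equal(mean(s$truth$z_true[!inS]), 0)
})

test_that("generation is deterministic in the seed and matches marginals", {
  cfg <- synthetic_config(n = 50000, variables = c("RACE", "SERVICES", "LOS"))
  a <- sample_cohort(cfg, seed = 9)
  b <- sample_cohort(cfg, seed = 9)
  expect_identical(a$cohort$data, b$cohort$data)
  expect_identical(a$truth, b$truth)
  c2 <- sample_cohort(cfg, seed = 10)
  expect_false(identical(a$cohort$data, c2$cohort$data))
  # chi-square goodness of fit against the configured marginals
  for (vn in c("RACE", "SERVICES", "LOS")) {
    m <- cfg$marginals[[vn]]
    obs <- table(factor(a$cohort$data[[vn]], levels = names(m)))
    keep <- m > 0
    p <- suppressWarnings(stats::chisq.test(obs[keep], p = m[keep] / sum(m[keep]))$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("config validation catches bad references and probabilities", {
  expect_error(synthetic_config(n = 10, variables = "GENDER",
                                beta_x = list(WAT = c(`1` = 1))), "WAT")
  expect_error(synthetic_config(n = 10, variables = "GENDER",
                                beta_x = list(GENDER = c(`9` = 1))), "category 9")
  expect_error(synthetic_config(n = 10, variables = "GENDER",
                                interactions = list(list(predicate = list(GENDER = 99L),
                                                         gamma = 1))), "99")
  expect_error(synthetic_config(n = 10, variables = "GENDER",
                                marginals = list(GENDER = c(`1` = 0.7, `2` = 0.7))),
               "summing to 1")
  expect_error(synthetic_config(n = 0, variables = "GENDER"), ">= 1")
})
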