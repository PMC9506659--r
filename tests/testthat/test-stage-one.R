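test_that("splits have the stated sizes, are seeded, and cover the sample", {
  sp <- split_train_test(10, frac = 0.7, seed = 1)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_identical(split_train_test(10, frac = 0.7, seed = 1), sp)
  expect_error(split_train_test(5), "at least 10")
  expect_error(split_train_test(100, frac = 1.2), "frac")
  # over 10 seeded iterations, held-out sets cover nearly all rows
  covered <- unique(unlist(lapply(1:10, function(s) {
    split_train_test(1000, seed = s)$test
  })))
  expect_gt(length(covered) / 1000, 0.95)
})

test_that("a separable problem is fit perfectly by the logistic learner", {
  x <- cbind(a = c(rep(0, 20), rep(1, 20)), b = rep(c(0, 1), 20))
  y <- as.integer(x[, "a"] == 1)
  m <- fit_first_stage(x, y, learner_spec("logistic"), seed = 1)
  met <- evaluate_model(m, x, y)
  expect_equal(unname(met["accuracy"]), 1)
  expect_equal(unname(met["auc"]), 1)
  expect_error(fit_first_stage(x, rep(1L, 40), learner_spec("logistic")),
               "single class")
})

test_that("metrics match hand-computed confusion counts and conventions", {
  y <- c(rep(1L, 4), rep(0L, 6))
  probs <- c(0.9, 0.9, 0.9, 0.1, 0.9, 0.1, 0.1, 0.1, 0.1, 0.1)
  met <- evaluate_model(probs, outcome = y)  # TP=3 FP=1 FN=1 TN=5
  expect_equal(unname(met["precision"]), 0.75)
  expect_equal(unname(met["recall"]), 0.75)
  expect_equal(unname(met["f1"]), 0.75)
  expect_equal(unname(met["accuracy"]), 0.8)
  # perfect probabilities
  expect_equal(unname(evaluate_model(y, outcome = y)), c(1, 1, 1, 1, 1))
  # an uninformative constant scorer has AUC 1/2 under the tie convention
  expect_equal(unname(evaluate_model(rep(0.5, 10), outcome = y)["auc"]), 0.5)
  # F1 is the harmonic mean of precision and recall whenever defined
  set.seed(42)
  for (i in 1:20) {
    yy <- rbinom(50, 1, 0.4)
    pp <- runif(50)
    m2 <- evaluate_model(pp, outcome = yy)
    if (m2["precision"] + m2["recall"] > 0) {
      expect_equal(unname(m2["f1"]),
                   2 * m2[["precision"]] * m2[["recall"]] /
                     (m2[["precision"]] + m2[["recall"]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  y <- rbinom(200, 1, 0.35)
  probs <- plogis(rnorm(200) + y)
  ours <- unname(evaluate_model(probs, outcome = y)["auc"])
  ref <- as.numeric(pROC::auc(pROC::roc(y, probs, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("outcome-independent designs score near chance AUC out of sample", {
  set.seed(31)
  x <- matrix(rbinom(5000 * 8, 1, 0.5), 5000, 8,
              dimnames = list(NULL, paste0("c", 1:8)))
  y <- rbinom(5000, 1, 0.4)
  sp <- split_train_test(5000, seed = 1)
  m <- fit_first_stage(x[sp$train, ], y[sp$train], learner_spec("logistic"), seed = 1)
  met <- evaluate_model(m, x[sp$test, ], y[sp$test])
  expect_lt(abs(met[["auc"]] - 0.5), 0.05)
})

test_that("held-out AUC grows with planted effect strength (on average)", {
  aucs <- sapply(c(0, 0.5, 1.5), function(strength) {
    mean(sapply(1:3, function(s) {
      cfg <- synthetic_config(n = 1500, variables = c("FREQ1_D", "NOPRIOR", "GENDER"),
                              beta0 = -0.6,
                              beta_x = if (strength > 0)
                                list(FREQ1_D = c(`1` = strength, `3` = -strength))
                              else list())
      sam <- sample_cohort(cfg, seed = 100 + s)
      d <- build_design(sam$cohort)
      y <- code_outcome(sam$cohort)
      sp <- split_train_test(nrow(d$x), seed = s)
      m <- fit_first_stage(d$x[sp$train, ], y[sp$train],
                           learner_spec("random_forest", num_trees = 100), seed = s)
      evaluate_model(m, d$x[sp$test, ], y[sp$test])[["auc"]]
    }))
  })
  expect_true(all(diff(aucs) > 0))
})

test_that("model selection maximizes AUC with documented tie-breaks", {
  mk_eval <- function(df, roster) {
    attr(df, "roster") <- roster
    class(df) <- c("vt_eval", "data.frame")
    df
  }
  row <- function(l, acc, auc, f1) {
    data.frame(learner = l, iteration = 1, accuracy = acc, auc = auc,
               precision = f1, recall = f1, f1 = f1)
  }
  # single learner
  expect_equal(as.character(select_model(mk_eval(row("only", .7, .7, .7), "only"))),
               "only")
  # dominance on all three metrics
  ev <- mk_eval(rbind(row("a", .8, .9, .8), row("b", .7, .8, .7)), c("b", "a"))
  expect_equal(as.character(select_model(ev)), "a")
  # AUC tie broken by F1
  ev <- mk_eval(rbind(row("a", .7, .8, .9), row("b", .9, .8, .7)), c("a", "b"))
  expect_equal(as.character(select_model(ev)), "a")
  # full tie broken by declaration order, not alphabet
  ev <- mk_eval(rbind(row("zeta", .8, .8, .8), row("alpha", .8, .8, .8)),
                c("zeta", "alpha"))
  expect_equal(as.character(select_model(ev)), "zeta")
  # invariance to row order except through declaration order
  ev2 <- mk_eval(rbind(row("alpha", .8, .8, .8), row("zeta", .8, .8, .8)),
                 c("zeta", "alpha"))
  expect_equal(as.character(select_model(ev2)), "zeta")
})

test_that("importance concentrates on the driving variable and scales to 1", {
  # permutation importance on a hand-built model that uses COLOR only
  ch <- random_toy_cohort(400, seed = 6)
  d <- build_design(ch)
  m <- logistic_model(intercept = -0.5, coefficients = c(`COLOR=1` = 2),
                      feature_names = colnames(d$x))
  set.seed(13)
  y <- as.integer(runif(400) < predict_prob(m, d))
  imp <- scaled_importance(m, d, outcome = y, seed = 1)
  expect_equal(imp$scaled[imp$variable == "COLOR"], 1)
  expect_true(all(imp$scaled[imp$variable != "COLOR"] < 0.2))
  # impurity importance from a forest on a strongly driven synthetic outcome
  cfg <- synthetic_config(n = 3000, variables = c("SERVICES_D", "GENDER", "NOPRIOR"),
                          beta0 = -0.5,
                          beta_x = list(SERVICES_D = c(`6` = 1.5, `7` = 1.5)))
  s <- sample_cohort(cfg, seed = 8)
  d2 <- build_design(s$cohort)
  y2 <- code_outcome(s$cohort)
  rf <- fit_first_stage(d2, y2, learner_spec("random_forest", num_trees = 100), seed = 1)
  imp2 <- scaled_importance(rf, d2)
  expect_equal(imp2$variable[1], "SERVICES_D")
  expect_equal(imp2$scaled[1], 1)
  expect_equal(sum(imp2$scaled == 1), 1)
})

test_that("SMOTE balances to parity with valid one-hot patterns", {
  ch <- random_toy_cohort(120, seed = 10)
  d <- build_design(ch)
  y <- c(rep(1L, 20), rep(0L, 100))
  bal <- smote_balance(d$x, y, seed = 1, variables = d$variables)
  expect_equal(as.vector(table(bal$y)), c(100, 100))
  synth <- bal$x[(nrow(d$x) + 1):nrow(bal$x), , drop = FALSE]
  for (vn in names(d$variables)) {
    block <- synth[, d$variables[[vn]]$columns, drop = FALSE]
    expect_true(all(abs(rowSums(block) - 1) < 1e-12))
    expect_true(all(block %in% c(0, 1)))
  }
  # balanced input is a no-op
  yb <- rep(c(0L, 1L), 60)
  expect_identical(smote_balance(d$x, yb, seed = 1)$x, d$x)
  # minority smaller than the neighborhood errors with advice
  expect_error(smote_balance(d$x, c(rep(1L, 3), rep(0L, 117)), k_neighbors = 5),
               "smaller k")
})
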