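test_that("constant differences give a root-only tree", {
  p <- random_tree_problem(200, seed = 1)
  tr <- fit_difference_tree(rep(0.07, 200), p$design, tree_params())
  expect_length(tr$nodes, 1)
  expect_equal(tr$nodes[[1]]$mean_z, 0.07)
  expect_equal(tr$nodes[[1]]$frac, 1)
  expect_equal(tr$nodes[[1]]$depth, 0L)
})

test_that("a noise-free planted split is recovered exactly at depth 1", {
  # SERVICES_D-style variable: z = 0.10 inside the ambulatory category set
  cb <- codebook(list(
    list(name = "SERVICES_D", categories = c(`1` = "detox", `2` = "rehab",
                                             `3` = "ambulatory")),
    list(name = "GENDER", categories = c(`1` = "male", `2` = "female")),
    list(name = "LOS", categories = c(`1` = "short", `2` = "medium", `3` = "long"))
  ))
  set.seed(3)
  data <- data.frame(SERVICES_D = sample(1:3, 300, TRUE),
                     GENDER = sample(1:2, 300, TRUE),
                     LOS = sample(1:3, 300, TRUE))
  ch <- vtdisparity:::as_cohort(data, cb)
  d <- build_design(ch)
  z <- ifelse(data$SERVICES_D == 3, 0.10, 0)
  tr <- fit_difference_tree(z, d, tree_params())
  expect_length(tr$nodes, 3)
  root <- tr$nodes[[1]]
  expect_equal(root$var, "SERVICES_D")
  expect_true(subgroup_matches(tr, root$children[1], list(SERVICES_D = 3L), cb) ||
                subgroup_matches(tr, root$children[2], list(SERVICES_D = 3L), cb))
  leaf_means <- sort(vapply(tree_leaves(tr), `[[`, 0, "mean_z"))
  expect_equal(leaf_means, c(0, 0.10))
})

test_that("leaf means conserve the root mean (weighted)", {
  for (s in 1:20) {
    p <- random_tree_problem(400, k = 3, seed = s)
    tr <- fit_difference_tree(p$z, p$design, tree_params(max_depth = 4, cp = 1e-6))
    leaves <- tree_leaves(tr)
    agg <- sum(vapply(leaves, function(nd) nd$frac * nd$mean_z, 0))
    expect_lt(abs(agg - tr$nodes[[1]]$mean_z), 1e-9)
    expect_equal(sum(vapply(leaves, `[[`, 0L, "n")), tr$n)
    # children partition parents throughout the tree
    for (nd in tr$nodes) {
      if (length(nd$children)) {
        expect_equal(sum(vapply(tr$nodes[nd$children], `[[`, 0L, "n")), nd$n)
      }
    }
  }
})

test_that("the root split matches exhaustive best-subset search", {
  for (s in 1:10) {
    p <- random_tree_problem(150, k = 3, seed = 100 + s)
    params <- tree_params(max_depth = 1, min_leaf_frac = 0.05, cp = 0)
    tr <- fit_difference_tree(p$z, p$design, params)
    min_leaf <- ceiling(0.05 * 150)
    oracle <- brute_force_best_reduction(p$z, p$design, min_leaf)
    got <- root_split_reduction(tr, p$design, p$z)
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("missingness can define a recovered subgroup", {
  cb <- codebook(list(
    list(name = "A", categories = c(`1` = "x", `2` = "y")),
    list(name = "B", categories = c(`1` = "u", `2` = "v"))
  ))
  set.seed(5)
  data <- data.frame(A = sample(c(1L, 2L, NA), 200, TRUE),
                     B = sample(1:2, 200, TRUE))
  ch <- vtdisparity:::as_cohort(data, cb)
  d <- build_design(ch)
  z <- ifelse(is.na(data$A), 0.2, 0)
  tr <- fit_difference_tree(z, d, tree_params())
  expect_equal(tr$nodes[[1]]$var, "A")
  expect_true(tr$nodes[[1]]$yes_missing)
  expect_equal(length(tr$nodes[[1]]$yes_codes), 0)
})

test_that("subgroup extraction ranks by |mean| and separates low support", {
  p <- random_tree_problem(300, seed = 7)
  tr <- fit_difference_tree(p$z, p$design,
                            tree_params(max_depth = 3, min_leaf_frac = 0.004, cp = 0))
  sg <- extract_subgroups(tr, min_frac = 0.05)
  expect_true(all(sg$subgroups$frac >= 0.05))
  expect_true(all(sg$low_support$frac < 0.05))
  expect_true(!is.unsorted(rev(abs(sg$subgroups$mean_z))))
  expect_equal(nrow(sg$subgroups) + nrow(sg$low_support), length(tr$nodes))
  # a root-only tree reports a single full-sample node
  tr0 <- fit_difference_tree(rep(0.5, 300), p$design, tree_params())
  sg0 <- extract_subgroups(tr0)
  expect_equal(nrow(sg0$subgroups), 1)
  expect_equal(sg0$subgroups$frac, 1)
  expect_equal(sg0$subgroups$rule, "(root)")
})

test_that("renders show yes-first branches and valid DOT syntax", {
  cb <- codebook(list(list(name = "A", categories = c(`1` = "x", `2` = "y"))))
  data <- data.frame(A = rep(1:2, each = 50))
  ch <- vtdisparity:::as_cohort(data, cb)
  d <- build_design(ch)
  z <- ifelse(data$A == 1, 0.3, -0.1)
  tr <- fit_difference_tree(z, d, tree_params())
  txt <- render_tree(tr, "text")
  expect_length(txt, 3)
  expect_match(txt[2], "\\[yes\\]")
  expect_match(txt[3], "\\[no\\]")
  dot <- render_tree(tr, "dot")
  expect_match(dot[1], "^digraph")
  expect_equal(sum(grepl("\\{", dot)), sum(grepl("\\}", dot)))
  expect_equal(sum(grepl("->", dot)), 2)
  expect_error(render_tree(tr, "svg"), "arg")
  # single-node document for a root-only tree
  tr0 <- fit_difference_tree(rep(0, 100), d, tree_params())
  expect_length(render_tree(tr0, "text"), 1)
})

test_that("tree fitting is deterministic given identical inputs", {
  p <- random_tree_problem(250, seed = 9)
  t1 <- fit_difference_tree(p$z, p$design, tree_params())
  t2 <- fit_difference_tree(p$z, p$design, tree_params())
  expect_identical(t1, t2)
})
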