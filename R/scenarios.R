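#' Reference simulation scenarios
#'
#' Two fixed study conditions used throughout the package's validation:
#' \describe{
#'   \item{planted}{A single subgroup interaction on the binary attribute:
#'     discharges with no primary-substance use in the month before discharge
#'     (about 54% of records under the packaged marginals) complete more
#'     often when focal. The interaction strength is calibrated so the exact
#'     mean true twin difference inside the subgroup equals `target_delta`
#'     (default 0.08 on the probability scale); outside the subgroup the
#'     true difference is 0. The subgroup variable's categories all carry
#'     substantial mass, so a recovered split can in principle reproduce the
#'     planted category set exactly (variables with near-empty categories
#'     cannot be recovered exactly: categories rarer than the minimum leaf
#'     size attach arbitrarily to one side of a split).}
#'   \item{null}{The same outcome model with no attribute effect at all
#'     (`beta_T = 0`, no interaction), so the true twin difference is 0 for
#'     every record.}
#' }
#' Both use the packaged full-sample marginals, an intercept placing the
#' baseline completion rate near the published 33.8%, main effects on
#' discharge-time use frequency, prior treatment episodes and length of stay,
#' and attribute prevalence 0.435 (the no-co-occurring-disorder share).
#' Covariates are restricted to eleven demographically and clinically central
#' variables so repeated model fits stay affordable at n = 20,000.
#'
#' @param effect `"planted"` or `"null"`.
#' @param n Cohort size.
#' @param target_delta Calibrated mean in-subgroup true twin difference
#'   (probability scale) for the planted scenario.
#' @return A `vt_synthetic_config` with attributes `predicate` (the planted
#'   subgroup, `NULL` for null) and `truth_delta` (its exact mean true twin
#'   difference).
#' @export
synthetic_scenario <- function(effect = c("planted", "null"), n = 20000,
                               target_delta = 0.08) {
  effect <- match.arg(effect)
  vars <- c("GENDER", "AGE", "SERVICES", "SERVICES_D", "LOS", "FREQ1",
            "FREQ1_D", "SUB1", "PSOURCE", "NOPRIOR", "EMPLOY_D")
  marg <- default_marginals()[vars]
  beta_x <- list(
    FREQ1_D = c(`1` = 0.5, `3` = -0.4),
    NOPRIOR = c(`1` = -0.3),
    LOS = c(`7` = 0.3, `8` = 0.3)
  )
  predicate <- list(FREQ1_D = 1L)
  base_cfg <- function(interactions) {
    synthetic_config(
      n = n, variables = vars, marginals = marg,
      treated_attr = "T", p_treated = 0.435,
      beta0 = stats::qlogis(0.338), beta_T = 0,
      beta_x = beta_x, interactions = interactions
    )
  }
  if (effect == "null") {
    cfg <- base_cfg(list())
    attr(cfg, "predicate") <- NULL
    attr(cfg, "truth_delta") <- 0
    return(cfg)
  }
  gap <- function(g) {
    expected_subgroup_z(base_cfg(list(list(predicate = predicate, gamma = g))),
                        predicate) - target_delta
  }
  gamma <- stats::uniroot(gap, c(1e-6, 5), tol = 1e-10)$root
  cfg <- base_cfg(list(list(predicate = predicate, gamma = gamma)))
  attr(cfg, "predicate") <- predicate
  attr(cfg, "truth_delta") <- expected_subgroup_z(cfg, predicate)
  cfg
}

#' One validation replicate of a reference scenario
#'
#' Runs the full two-stage procedure once on a freshly sampled scenario
#' cohort: stage-one fit of the twin model on the full analysis sample,
#' counterfactual twin prediction, difference-tree fit, and subgroup
#' extraction. Used by the package's recovery and null-safety validations.
#' The default twin model is a probability random forest with
#' `mtry = floor(p / 3)` (regression-style); with `mtry = sqrt(p)` over
#' one-hot indicator columns the single indicator column is rarely offered
#' to a split, which visibly attenuates the counterfactual difference (see
#' the package vignette).
#'
#' @param effect `"planted"` or `"null"` (see [synthetic_scenario()]).
#' @param seed Integer seed for sampling and fitting.
#' @param n Cohort size.
#' @param learner A `vt_learner_spec` for the twin model, or `NULL` for the
#'   default described above.
#' @param params Difference-tree parameters.
#' @return A list: `recovered` (was any reported subgroup exactly the
#'   planted predicate; `NA` for the null scenario), `node_mean` (mean twin
#'   difference of the recovered node), `truth` (exact in-subgroup mean true
#'   difference), `max_abs_leaf_mean`, `n_nodes`, and the fitted `tree`.
#' @export
scenario_replicate <- function(effect = c("planted", "null"), seed, n = 20000,
                               learner = NULL, params = tree_params()) {
  effect <- match.arg(effect)
  cfg <- synthetic_scenario(effect, n)
  s <- sample_cohort(cfg, seed = seed)
  ct <- synthetic_contrast(cfg$treated_attr)
  d1 <- build_design(s$cohort, ct, "one")
  d2 <- build_design(s$cohort, ct, "two")
  y <- code_outcome(s$cohort)[d1$rows]
  if (is.null(learner)) {
    learner <- learner_spec("random_forest", mtry = max(1L, floor(ncol(d1$x) / 3)))
  }
  model <- fit_first_stage(d1, y, learner, seed = seed)
  twins <- predict_twins(model, d1)
  tree <- fit_difference_tree(twins, d2, params)
  sg <- extract_subgroups(tree)
  pred <- attr(cfg, "predicate")
  recovered <- NA
  node_mean <- NA_real_
  if (!is.null(pred)) {
    recovered <- FALSE
    for (i in seq_len(nrow(sg$subgroups))) {
      if (subgroup_matches(tree, sg$subgroups$node[i], pred, s$cohort$codebook)) {
        recovered <- TRUE
        node_mean <- sg$subgroups$mean_z[i]
        break
      }
    }
  }
  leaves <- Filter(function(nd) !length(nd$children), tree$nodes)
  list(recovered = recovered, node_mean = node_mean,
       truth = attr(cfg, "truth_delta"),
       max_abs_leaf_mean = max(abs(vapply(leaves, `[[`, 0, "mean_z"))),
       n_nodes = length(tree$nodes), tree = tree)
}

#' Contrast for the synthetic binary attribute
#'
#' @param treated_attr Name of the attribute column in the synthetic cohort.
#' @return A `vt_contrast` whose focal group is `T = 1`.
#' @export
synthetic_contrast <- function(treated_attr = "T") {
  disparity_contrast("synthetic_attr",
                     stats::setNames(list(1L), treated_attr))
}
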