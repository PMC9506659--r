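#' Specify a first-stage learner
#'
#' Four completion-probability learners are supported: a probability random
#' forest, gradient boosted trees, a single-hidden-layer neural network, and
#' logistic regression. Defaults are explicit and configurable:
#' \describe{
#'   \item{random_forest}{200 trees, `mtry = floor(sqrt(p))`, minimum node
#'     size 10, impurity importance.}
#'   \item{gradient_boosted_trees}{100 rounds, learning rate 0.3, max depth 6.}
#'   \item{neural_net}{64 rectifier-free (logistic) hidden units, weight decay
#'     1e-4, 100 BFGS iterations.}
#'   \item{logistic}{unpenalized binomial GLM; one-hot collinearity is
#'     resolved by aliasing redundant columns to zero.}
#' }
#'
#' @param kind One of `"random_forest"`, `"gradient_boosted_trees"`,
#'   `"neural_net"`, `"logistic"`.
#' @param ... Hyperparameter overrides (validated against the kind's schema).
#' @return A `vt_learner_spec`.
#' @export
learner_spec <- function(kind = c("random_forest", "gradient_boosted_trees",
                                  "neural_net", "logistic"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    random_forest = list(num_trees = 200L, mtry = NULL, min_node_size = 10L),
    gradient_boosted_trees = list(nrounds = 100L, eta = 0.3, max_depth = 6L),
    neural_net = list(hidden = 64L, decay = 1e-4, maxit = 100L),
    logistic = list()
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) {
    stop("unknown hyperparameter(s) for ", kind, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(override)] <- override
  structure(list(kind = kind, hyperparameters = defaults), class = "vt_learner_spec")
}

#' Seeded train/test split
#'
#' @param n Number of rows (or a `vt_design`).
#' @param frac Training fraction; `|train| = round(frac * n)`.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return A list with disjoint, exhaustive integer index vectors `train`
#'   and `test`.
#' @export
split_train_test <- function(n, frac = 0.7, seed = 1) {
  if (inherits(n, "vt_design")) n <- nrow(n$x)
  if (n < 10) stop("need at least 10 rows to split", call. = FALSE)
  if (frac <= 0 || frac >= 1) stop("`frac` must be in (0, 1)", call. = FALSE)
  k <- round(frac * n)
  if (k < 1 || k >= n) stop("degenerate split for n = ", n, call. = FALSE)
  train <- with_seed(seed, sort(sample.int(n, k)))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Fit a first-stage completion-probability model
#'
#' @param design A `vt_design` (stage one) or a numeric matrix.
#' @param outcome Binary outcome vector (0/1), one per design row.
#' @param spec A `vt_learner_spec`.
#' @param seed Integer seed; training is fully seeded.
#' @return A `vt_model` exposing [predict_prob()].
#' @export
fit_first_stage <- function(design, outcome, spec = learner_spec("random_forest"),
                            seed = 1) {
  x <- if (inherits(design, "vt_design")) design$x else design
  outcome <- as.integer(outcome)
  if (length(outcome) != nrow(x)) stop("outcome length != design rows", call. = FALSE)
  if (anyNA(outcome)) stop("outcome contains NA; exclude those records first", call. = FALSE)
  classes <- sort(unique(outcome))
  if (length(classes) < 2) {
    stop("outcome has a single class (", classes, "); cannot fit", call. = FALSE)
  }
  hp <- spec$hyperparameters
  fit <- with_seed(seed, switch(spec$kind,
    random_forest = {
      ranger::ranger(
        x = x, y = factor(outcome, levels = c(0, 1)),
        probability = TRUE,
        num.trees = hp$num_trees,
        mtry = hp$mtry %||% max(1L, floor(sqrt(ncol(x)))),
        min.node.size = hp$min_node_size,
        importance = "impurity",
        seed = seed, num.threads = 1L
      )
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(x, label = outcome)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$eta,
                      max_depth = hp$max_depth, nthread = 1L),
        data = dtrain, nrounds = hp$nrounds, verbose = 0
      )
    },
    neural_net = {
      nw <- (ncol(x) + 1L) * hp$hidden + hp$hidden + 1L
      nnet::nnet(x = x, y = outcome, size = hp$hidden, decay = hp$decay,
                 maxit = hp$maxit, entropy = TRUE, trace = FALSE,
                 MaxNWts = nw + 10L)
    },
    logistic = {
      xf <- cbind(`(Intercept)` = 1, x)
      g <- stats::glm.fit(xf, outcome, family = stats::binomial())
      coefs <- g$coefficients
      coefs[is.na(coefs)] <- 0
      list(coefficients = coefs)
    }
  ))
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 feature_names = colnames(x)),
            class = "vt_model")
}

#' Predict completion probabilities
#'
#' @param model A `vt_model`.
#' @param x A `vt_design` or numeric matrix with the model's feature columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, x) {
  if (inherits(x, "vt_design")) x <- x$x
  miss <- setdiff(model$feature_names, colnames(x))
  if (length(miss)) stop("design lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  x <- x[, model$feature_names, drop = FALSE]
  switch(model$kind,
    random_forest = stats::predict(model$fit, data = x,
                                   num.threads = 1L)$predictions[, "1"],
    gradient_boosted_trees = stats::predict(model$fit, xgboost::xgb.DMatrix(x)),
    neural_net = as.numeric(stats::predict(model$fit, x)),
    logistic = ,
    fixed_logistic = {
      co <- model$fit$coefficients
      eta <- co[["(Intercept)"]] +
        as.numeric(x[, setdiff(names(co), "(Intercept)"), drop = FALSE] %*%
                     co[setdiff(names(co), "(Intercept)")])
      sigmoid(eta)
    }
  )
}

#' A logistic model with hand-specified coefficients
#'
#' Constructs a probability model from fixed log-odds coefficients (no
#' fitting), useful for closed-form checks of the counterfactual machinery.
#'
#' @param intercept Intercept on the log-odds scale.
#' @param coefficients Named numeric vector of per-column log-odds
#'   coefficients; columns of the design not named here get 0.
#' @param feature_names Feature columns the model expects (defaults to the
#'   coefficient names).
#' @return A `vt_model`.
#' @export
logistic_model <- function(intercept = 0, coefficients = numeric(),
                           feature_names = names(coefficients)) {
  co <- c(`(Intercept)` = intercept, coefficients)
  structure(list(kind = "fixed_logistic",
                 spec = list(kind = "fixed_logistic", hyperparameters = list()),
                 fit = list(coefficients = co),
                 feature_names = feature_names),
            class = "vt_model")
}

#' Held-out classification metrics
#'
#' Accuracy, precision, recall and F1 at the classification threshold, and
#' rank-based AUC (tied scores count one half concordant). Precision and
#' recall are 0 when their denominator is empty, and F1 is 0 when precision
#' and recall are both 0.
#'
#' @param model A `vt_model`, or a numeric probability vector.
#' @param x Design/matrix for prediction (ignored when `model` is already a
#'   probability vector).
#' @param outcome Binary labels.
#' @param threshold Classification threshold (default 0.5).
#' @return Named numeric vector: `accuracy`, `auc`, `precision`, `recall`,
#'   `f1`.
#' @export
evaluate_model <- function(model, x = NULL, outcome, threshold = 0.5) {
  probs <- if (inherits(model, "vt_model")) predict_prob(model, x) else as.numeric(model)
  y <- as.integer(outcome)
  stopifnot(length(probs) == length(y))
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(accuracy = (tp + tn) / length(y),
    auc = auc_rank(probs, y),
    precision = precision, recall = recall, f1 = f1)
}

#' Compare learners over repeated train/test splits
#'
#' Runs each learner over `iterations` random 70/30 splits (seeds
#' `seed + 0 .. iterations - 1`, shared across learners so splits are
#' paired), computing held-out metrics each time.
#'
#' @param design A stage-one `vt_design` (or matrix).
#' @param outcome Binary outcome per design row.
#' @param specs Named list of `vt_learner_spec`s (declaration order is the
#'   final tie-break in [select_model()]).
#' @param iterations Number of split iterations (the published analysis used
#'   10).
#' @param frac Training fraction (default 0.7).
#' @param seed Base seed.
#' @param smote Apply [smote_balance()] to each training split before
#'   fitting (robustness variant).
#' @return A `vt_eval`: data frame of per-iteration held-out metrics with
#'   attribute `roster` preserving declaration order.
#' @export
compare_learners <- function(design, outcome,
                             specs = default_learner_roster(),
                             iterations = 10, frac = 0.7, seed = 1,
                             smote = FALSE) {
  x <- if (inherits(design, "vt_design")) design$x else design
  variables <- if (inherits(design, "vt_design")) design$variables else NULL
  outcome <- as.integer(outcome)
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, `[[`, "", "kind")
  }
  rows <- list()
  for (it in seq_len(iterations)) {
    sp <- split_train_test(nrow(x), frac = frac, seed = seed + it - 1L)
    xtr <- x[sp$train, , drop = FALSE]; ytr <- outcome[sp$train]
    if (smote) {
      bal <- smote_balance(xtr, ytr, seed = seed + it - 1L, variables = variables)
      xtr <- bal$x; ytr <- bal$y
    }
    for (ln in names(specs)) {
      m <- fit_first_stage(xtr, ytr, specs[[ln]], seed = seed + it - 1L)
      met <- evaluate_model(m, x[sp$test, , drop = FALSE], outcome[sp$test])
      rows[[length(rows) + 1L]] <- data.frame(
        learner = ln, iteration = it, t(met))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "roster") <- names(specs)
  class(out) <- c("vt_eval", "data.frame")
  out
}

#' Default learner roster
#'
#' The four learners compared in the first stage, in declaration order.
#' @return Named list of `vt_learner_spec`s.
#' @export
default_learner_roster <- function() {
  list(random_forest = learner_spec("random_forest"),
       gradient_boosted_trees = learner_spec("gradient_boosted_trees"),
       neural_net = learner_spec("neural_net"),
       logistic = learner_spec("logistic"))
}

#' Aggregate evaluation metrics per learner
#'
#' @param eval A `vt_eval`.
#' @return Data frame of per-learner means and standard deviations, in
#'   roster order.
#' @export
summarize_eval <- function(eval) {
  roster <- attr(eval, "roster") %||% unique(eval$learner)
  metrics <- c("accuracy", "auc", "precision", "recall", "f1")
  out <- do.call(rbind, lapply(roster, function(ln) {
    s <- eval[eval$learner == ln, metrics, drop = FALSE]
    stats <- c(colMeans(s), stats::setNames(vapply(s, stats::sd, 0), paste0(metrics, "_sd")))
    data.frame(learner = ln, t(stats))
  }))
  rownames(out) <- NULL
  out
}

#' Select the finalist learner
#'
#' Picks the learner with the highest mean held-out AUC; ties are broken by
#' mean F1, then mean accuracy, then declaration order. (On the published
#' cohort the random forest dominated on accuracy, AUC and F1.)
#'
#' @param eval A `vt_eval` from [compare_learners()].
#' @return The winning learner's name, with the per-learner summary attached
#'   as attribute `summary`.
#' @export
select_model <- function(eval) {
  s <- summarize_eval(eval)
  ord <- order(-s$auc, -s$f1, -s$accuracy, seq_len(nrow(s)))
  winner <- s$learner[ord[1]]
  structure(winner, summary = s)
}

#' Scaled per-variable feature importance
#'
#' Importances of a variable's one-hot columns (including its missing
#' indicator) are summed to a per-variable raw importance, then scaled by the
#' maximum so the most important variable scores 1. Tree ensembles use
#' impurity/gain importance; other learners use permutation importance
#' (mean AUC drop over `n_rep` block permutations on the supplied, ideally
#' held-out, data). Negative raw importances are clamped to 0.
#'
#' @param model A `vt_model`.
#' @param design The `vt_design` the model was fitted on (used for the
#'   column-to-variable map and, for permutation importance, the data).
#' @param outcome Outcome labels (required for permutation importance).
#' @param seed Seed for permutation importance.
#' @param n_rep Permutation repetitions.
#' @return Data frame `variable`, `raw`, `scaled`, sorted by `scaled`
#'   descending.
#' @export
scaled_importance <- function(model, design, outcome = NULL, seed = 1, n_rep = 3) {
  stopifnot(inherits(design, "vt_design"))
  col_raw <- switch(model$kind,
    random_forest = {
      vi <- model$fit$variable.importance
      stats::setNames(as.numeric(vi), names(vi))
    },
    gradient_boosted_trees = {
      imp <- xgboost::xgb.importance(model = model$fit)
      stats::setNames(imp$Gain, imp$Feature)
    },
    permutation_importance(model, design, outcome, seed = seed, n_rep = n_rep)
  )
  raw <- vapply(names(design$variables), function(vn) {
    cols <- design$variables[[vn]]$columns
    sum(pmax(col_raw[intersect(cols, names(col_raw))], 0), na.rm = TRUE)
  }, 0)
  scaled <- if (max(raw) > 0) raw / max(raw) else raw
  out <- data.frame(variable = names(raw), raw = unname(raw), scaled = unname(scaled))
  out[order(-out$scaled), , drop = FALSE]
}

# Per-column permutation importance: AUC drop when a column block is permuted.
# Columns of one variable are permuted jointly (same permutation), so the
# block stays a valid one-hot pattern.
permutation_importance <- function(model, design, outcome, seed = 1, n_rep = 3) {
  if (is.null(outcome)) {
    stop("permutation importance needs `outcome`", call. = FALSE)
  }
  x <- design$x
  y <- as.integer(outcome)
  base <- auc_rank(predict_prob(model, x), y)
  out <- numeric(0)
  with_seed(seed, {
    for (vn in names(design$variables)) {
      cols <- design$variables[[vn]]$columns
      drops <- vapply(seq_len(n_rep), function(r) {
        xp <- x
        perm <- sample.int(nrow(x))
        xp[, cols] <- x[perm, cols, drop = FALSE]
        base - auc_rank(predict_prob(model, xp), y)
      }, 0)
      # spread the variable's importance uniformly over its columns; the
      # caller sums per variable so only the block total matters
      out[cols] <- mean(drops) / length(cols)
    }
  })
  out
}

#' SMOTE class balancing in one-hot space
#'
#' Oversamples the minority class to parity. Each synthetic row interpolates
#' between a minority row and one of its `k` nearest minority neighbors
#' (Euclidean distance in the indicator space), then snaps each variable's
#' indicator block back to the nearest valid one-hot pattern (the base row's
#' category when the interpolation weight is below one half, the neighbor's
#' otherwise). Apply to training data only.
#'
#' @param x Numeric indicator matrix (or `vt_design`).
#' @param y Binary outcome per row.
#' @param k_neighbors Number of nearest minority neighbors.
#' @param seed Integer seed.
#' @param variables Optional per-variable column metadata (taken from the
#'   design when `x` is a `vt_design`); used for block snapping. Columns not
#'   covered by any block are snapped individually to `{0, 1}`.
#' @return List with balanced `x` and `y`; balanced input is returned
#'   unchanged.
#' @export
smote_balance <- function(x, y, k_neighbors = 5, seed = 1, variables = NULL) {
  if (inherits(x, "vt_design")) {
    variables <- x$variables
    x <- x$x
  }
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present", call. = FALSE)
  if (tab[1] == tab[2]) return(list(x = x, y = y))
  minority <- as.integer(names(tab)[which.min(tab)])
  n_new <- abs(diff(as.integer(tab)))
  idx_min <- which(y == minority)
  if (length(idx_min) <= k_neighbors) {
    stop("minority class too small for k = ", k_neighbors,
         "; use a smaller k_neighbors", call. = FALSE)
  }
  xm <- x[idx_min, , drop = FALSE]
  nn <- knn_indices(xm, k_neighbors)
  with_seed(seed, {
    base <- sample.int(nrow(xm), n_new, replace = TRUE)
    pick <- vapply(base, function(b) nn[b, sample.int(k_neighbors, 1)], 0L)
    lambda <- stats::runif(n_new)
    synth <- xm[base, , drop = FALSE] * (1 - lambda) +
      xm[pick, , drop = FALSE] * lambda
    synth <- snap_one_hot(synth, variables, colnames(x))
    list(x = rbind(x, synth), y = c(y, rep(minority, n_new)))
  })
}

# k nearest neighbors among rows of xm (excluding self), chunked to bound
# memory on large minority classes.
knn_indices <- function(xm, k, chunk = 512L) {
  n <- nrow(xm)
  sq <- rowSums(xm^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * xm[idx, , drop = FALSE] %*% t(xm)
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

# Snap interpolated rows back to valid one-hot patterns per variable block.
snap_one_hot <- function(synth, variables, all_cols) {
  covered <- character(0)
  if (!is.null(variables)) {
    for (vn in names(variables)) {
      cols <- intersect(variables[[vn]]$columns, all_cols)
      if (length(cols) < 2) next
      block <- synth[, cols, drop = FALSE]
      win <- max.col(block, ties.method = "first")
      block[] <- 0
      block[cbind(seq_len(nrow(block)), win)] <- 1
      synth[, cols] <- block
      covered <- c(covered, cols)
    }
  }
  rest <- setdiff(all_cols, covered)
  if (length(rest)) {
    synth[, rest] <- round(synth[, rest, drop = FALSE])
  }
  synth
}
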