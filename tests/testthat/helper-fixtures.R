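# Small in-code fixtures shared across test files.

toy_codebook <- function() {
  codebook(list(
    list(name = "REASON", categories = c(`1` = "Treatment completed",
                                         `2` = "Dropped out", `3` = "Terminated by facility",
                                         `4` = "Transferred", `5` = "Incarcerated",
                                         `6` = "Death", `7` = "Other")),
    list(name = "COLOR", categories = c(`1` = "red", `2` = "green", `3` = "blue")),
    list(name = "SIZE", categories = c(`1` = "small", `2` = "large"))
  ), name = "toy")
}

toy_cohort <- function(data, cb = toy_codebook()) {
  vtdisparity:::as_cohort(data, cb, provenance = "toy")
}

# A random toy cohort with n records over the toy codebook (no missing).
random_toy_cohort <- function(n, seed = 1) {
  set.seed(seed)
  toy_cohort(data.frame(
    REASON = sample(1:7, n, replace = TRUE),
    COLOR = sample(1:3, n, replace = TRUE),
    SIZE = sample(1:2, n, replace = TRUE)
  ))
}

# Random small categorical design + response for tree tests:
# n rows, `k` variables with 2..4 categories each, z = group effects + noise.
random_tree_problem <- function(n, k = 3, seed = 1) {
  set.seed(seed)
  ncat <- sample(2:4, k, replace = TRUE)
  vars <- lapply(seq_len(k), function(j) {
    list(name = paste0("V", j),
         categories = stats::setNames(paste0("c", seq_len(ncat[j])),
                                      seq_len(ncat[j])))
  })
  cb <- codebook(vars, name = "tree-problem")
  data <- as.data.frame(lapply(seq_len(k), function(j) {
    sample(seq_len(ncat[j]), n, replace = TRUE)
  }), optional = TRUE)
  names(data) <- paste0("V", seq_len(k))
  cohort <- vtdisparity:::as_cohort(data, cb)
  design <- build_design(cohort)
  effects <- lapply(seq_len(k), function(j) stats::rnorm(ncat[j], sd = 0.5))
  z <- stats::rnorm(n, sd = 0.3)
  for (j in seq_len(k)) z <- z + effects[[j]][data[[j]]]
  list(design = design, z = z, cohort = cohort)
}

# Exhaustive best-subset root-split search: maximal SSE reduction over all
# variables and all non-empty proper subsets of each variable's observed
# levels (missing = level 0), honoring the minimum leaf size. Independent of
# the tree's sorted-means search.
brute_force_best_reduction <- function(z, design, min_leaf) {
  n <- length(z)
  best <- -Inf
  for (vn in names(design$data)) {
    x <- design$data[[vn]]
    x[is.na(x)] <- 0L
    lev <- sort(unique(x))
    if (length(lev) < 2) next
    for (mask in seq_len(2^length(lev) - 2)) {
      side <- lev[bitwAnd(mask, 2^(seq_along(lev) - 1)) > 0]
      inL <- x %in% side
      nl <- sum(inL); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      sl <- sum(z[inL]); sr <- sum(z) - sl
      red <- sl^2 / nl + sr^2 / nr - sum(z)^2 / n
      if (red > best) best <- red
    }
  }
  best
}

# SSE reduction achieved by a fitted tree's root split.
root_split_reduction <- function(tree, design, z) {
  root <- tree$nodes[[1]]
  if (!length(root$children)) return(NA_real_)
  x <- design$data[[root$var]]
  x[is.na(x)] <- 0L
  side <- c(root$yes_codes, if (root$yes_missing) 0L)
  inL <- x %in% side
  n <- length(z); nl <- sum(inL); nr <- n - nl
  sl <- sum(z[inL]); sr <- sum(z) - sl
  sl^2 / nl + sr^2 / nr - sum(z)^2 / n
}

# Leaf nodes of a fitted tree.
tree_leaves <- function(tree) {
  Filter(function(nd) !length(nd$children), tree$nodes)
}
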