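#' Counterfactual twin probabilities and their difference
#'
#' For every record of the stage-one design, predicts the completion
#' probability twice: once with the disparity indicator column forced to 1
#' and once forced to 0, all other columns untouched. The per-record
#' difference `z = p1 - p0` is the quantity the second stage explains.
#' Both predictions are made for every record regardless of its observed
#' indicator value, so flipping the observed indicator in the input leaves
#' the result unchanged.
#'
#' @param model A fitted `vt_model` trained on a design containing the
#'   indicator column.
#' @param design The stage-one `vt_design` (must carry `t_col`).
#' @return A `vt_twins` data frame with columns `p1`, `p0`, `z` and
#'   attribute `rows` (cohort row indices).
#' @export
predict_twins <- function(model, design) {
  stopifnot(inherits(design, "vt_design"))
  t_col <- design$t_col
  if (is.null(t_col) || !t_col %in% colnames(design$x)) {
    stop("design lacks an indicator column; build it with stage = \"one\"",
         call. = FALSE)
  }
  x1 <- design$x; x1[, t_col] <- 1
  x0 <- design$x; x0[, t_col] <- 0
  p1 <- predict_prob(model, x1)
  p0 <- predict_prob(model, x0)
  out <- data.frame(p1 = p1, p0 = p0, z = p1 - p0)
  attr(out, "rows") <- design$rows
  class(out) <- c("vt_twins", "data.frame")
  out
}

#' Difference-tree fit parameters
#'
#' Defaults give the shallow, readable trees the method reports: depth at
#' most 4, leaves no smaller than 0.5% of the analysis sample, and splits
#' kept only when they reduce the root-normalized sum of squares of `z` by
#' at least `cp`.
#'
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_leaf_frac Minimum leaf size as a fraction of the analysis
#'   sample.
#' @param cp Complexity penalty: minimum variance reduction
#'   (`delta SSE / n_root`) for a split to be kept.
#' @return A `vt_tree_params`.
#' @export
tree_params <- function(max_depth = 4, min_leaf_frac = 0.005, cp = 1e-4) {
  stopifnot(max_depth >= 0, min_leaf_frac > 0, min_leaf_frac < 0.5, cp >= 0)
  structure(list(max_depth = max_depth, min_leaf_frac = min_leaf_frac, cp = cp),
            class = "vt_tree_params")
}

#' Fit the second-stage difference tree
#'
#' Fits a binary regression tree to the per-record probability differences
#' `z` over the stage-two covariates. Every split is of the form
#' "variable in category-set" versus its complement; for each variable the
#' best category subset is found exactly by the classical sorted-means
#' reduction (order categories by their mean `z`, scan the K-1 contiguous
#' cuts), which is optimal for a single numeric response. Missingness
#' participates as an ordinary extra category, so missing-defined subgroups
#' can be found. Growth stops at `max_depth`, when a child would fall below
#' `min_leaf_frac`, or when the best split's variance reduction (delta SSE
#' over the root sample size) is below `cp`. The fit is deterministic; a
#' constant `z` yields a root-only tree. Ties in the split search are
#' resolved toward the earlier variable in design order and the smaller cut.
#'
#' @param z Numeric vector (or a `vt_twins`, whose `z` column is used).
#' @param design A stage-two `vt_design` over the same records.
#' @param params A [tree_params()].
#' @return A `vt_tree`: list of nodes with `id`, `parent`, `depth`, `n`,
#'   `frac`, `mean_z`, split rule (`var`, `yes_codes`, `yes_missing`), and
#'   children ids.
#' @export
fit_difference_tree <- function(z, design, params = tree_params()) {
  if (inherits(z, "vt_twins")) z <- z$z
  stopifnot(inherits(design, "vt_design"))
  data <- design$data
  if (length(z) != nrow(data)) stop("`z` length != design rows", call. = FALSE)
  n_root <- length(z)
  min_leaf <- max(1L, ceiling(params$min_leaf_frac * n_root))
  # categories encoded as integer levels; NA becomes level 0 ("missing")
  enc <- lapply(names(data), function(vn) {
    x <- data[[vn]]
    xi <- ifelse(is.na(x), 0L, as.integer(x))
    xi
  })
  names(enc) <- names(data)

  nodes <- list()
  new_node <- function(members, depth, parent, branch) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, branch = branch,
                         depth = depth, n = length(members),
                         frac = length(members) / n_root,
                         mean_z = mean(z[members]),
                         var = NA_character_, yes_codes = NULL,
                         yes_missing = FALSE, children = integer())
    grow(id, members, depth)
    id
  }
  grow <- function(id, members, depth) {
    if (depth >= params$max_depth) return(invisible())
    if (length(members) < 2L * min_leaf) return(invisible())
    best <- find_best_split(z, enc, members, min_leaf)
    if (is.null(best) || best$reduction / n_root < params$cp) return(invisible())
    yes <- members[best$yes_mask]
    no <- members[!best$yes_mask]
    info <- canonical_side(best)
    nodes[[id]]$var <<- best$var
    nodes[[id]]$yes_codes <<- info$codes
    nodes[[id]]$yes_missing <<- info$missing
    if (info$swapped) { tmp <- yes; yes <- no; no <- tmp }
    left <- new_node(yes, depth + 1L, id, "yes")
    right <- new_node(no, depth + 1L, id, "no")
    nodes[[id]]$children <<- c(left, right)
    invisible()
  }
  new_node(seq_len(n_root), 0L, NA_integer_, "root")
  structure(list(nodes = nodes, params = params, n = n_root,
                 variables = names(data)),
            class = "vt_tree")
}

# Best (variable, category-subset) split over `members` by SSE reduction.
# Returns NULL when no admissible split exists. `yes_mask` marks the
# lower-mean side of the chosen cut (canonicalized later).
find_best_split <- function(z, enc, members, min_leaf) {
  zm <- z[members]
  n <- length(zm)
  sum_all <- sum(zm)
  best <- NULL
  for (vn in names(enc)) {
    xv <- enc[[vn]][members]
    lev <- sort(unique(xv))
    if (length(lev) < 2) next
    grp <- match(xv, lev)
    ng <- tabulate(grp, length(lev))
    sg <- vapply(seq_along(lev), function(g) sum(zm[grp == g]), 0)
    ord <- order(sg / ng)
    csn <- cumsum(ng[ord]); css <- cumsum(sg[ord])
    for (j in seq_len(length(lev) - 1L)) {
      nl <- csn[j]; nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      sl <- css[j]; sr <- sum_all - sl
      reduction <- sl^2 / nl + sr^2 / nr - sum_all^2 / n
      if (is.null(best) || reduction > best$reduction + 1e-15) {
        left_lev <- lev[ord[seq_len(j)]]
        best <- list(var = vn, reduction = reduction,
                     left_levels = left_lev, levels = lev,
                     yes_mask = xv %in% left_lev)
      }
    }
  }
  best
}

# Canonical rule side: the branch condition names the smaller category set
# (ties: the side containing the smallest code), drawn from the levels
# observed in the node (0 encodes missing). Returns whether the yes-branch
# is the complement of the scanned lower-mean side.
canonical_side <- function(best) {
  left <- best$left_levels
  right <- setdiff(best$levels, left)
  pick_left <- length(left) < length(right) ||
    (length(left) == length(right) && min(left) <= min(right))
  side <- if (pick_left) left else right
  list(codes = sort(setdiff(side, 0L)), missing = 0L %in% side,
       swapped = !pick_left)
}

#' Extract and rank subgroups from a fitted tree
#'
#' Reports every node (internal and leaf) whose sample fraction is at least
#' `min_frac`, ranked by absolute mean difference; smaller nodes are
#' returned separately as low-support. Each node carries its human-readable
#' rule path from the root.
#'
#' @param tree A `vt_tree`.
#' @param min_frac Minimum fraction of the analysis sample for the main list
#'   (the reported subgroups use 1%).
#' @return A list with data frames `subgroups` and `low_support`, each with
#'   columns `node`, `depth`, `n`, `frac`, `mean_z`, `rule`.
#' @export
extract_subgroups <- function(tree, min_frac = 0.01) {
  rows <- do.call(rbind, lapply(tree$nodes, function(nd) {
    data.frame(node = nd$id, depth = nd$depth, n = nd$n, frac = nd$frac,
               mean_z = nd$mean_z, rule = rule_path_string(tree, nd$id))
  }))
  rows <- rows[order(-abs(rows$mean_z), rows$node), , drop = FALSE]
  rownames(rows) <- NULL
  list(subgroups = rows[rows$frac >= min_frac, , drop = FALSE],
       low_support = rows[rows$frac < min_frac, , drop = FALSE])
}

# Ordered list of (var, codes, missing, branch) clauses from root to node.
rule_path <- function(tree, id) {
  path <- list()
  nd <- tree$nodes[[id]]
  while (!is.na(nd$parent)) {
    par <- tree$nodes[[nd$parent]]
    path <- c(list(list(var = par$var, codes = par$yes_codes,
                        missing = par$yes_missing, branch = nd$branch)), path)
    nd <- par
  }
  path
}

rule_clause_string <- function(cl) {
  set <- c(as.character(cl$codes), if (cl$missing) "missing")
  paste0(cl$var, " in {", paste(set, collapse = ","), "} [", cl$branch, "]")
}

rule_path_string <- function(tree, id) {
  path <- rule_path(tree, id)
  if (!length(path)) return("(root)")
  paste(vapply(path, rule_clause_string, ""), collapse = " & ")
}

#' Does a node's rule match a subgroup predicate?
#'
#' Compares a node's rule path against a predicate (named list of
#' category-code sets) up to logical equivalence: a single-clause path
#' matches if its yes-side category set equals the predicate set (yes
#' branch) or its complement within the variable's observed categories
#' (no branch). Used to check planted-subgroup recovery.
#'
#' @param tree A `vt_tree`.
#' @param id Node id.
#' @param predicate Named list: variable -> integer code set.
#' @param codebook Codebook supplying each variable's category universe.
#' @return `TRUE` if the rule path is clause-for-clause equivalent to the
#'   predicate.
#' @export
subgroup_matches <- function(tree, id, predicate, codebook) {
  if (is.na(id) || id < 1 || id > length(tree$nodes)) return(FALSE)
  path <- rule_path(tree, id)
  if (length(path) != length(predicate)) return(FALSE)
  seen <- character(0)
  for (cl in path) {
    target <- predicate[[cl$var]]
    if (is.null(target) || cl$var %in% seen) return(FALSE)
    seen <- c(seen, cl$var)
    universe <- codebook$variables[[cl$var]]$codes
    yes_set <- cl$codes
    node_set <- if (cl$branch == "yes") yes_set else setdiff(universe, yes_set)
    # missing level: the predicate never includes missing records
    if (cl$branch == "yes" && cl$missing) return(FALSE)
    if (!setequal(node_set, target)) return(FALSE)
  }
  TRUE
}

#' Render a fitted difference tree
#'
#' Text renders show per-node mean difference (3 decimals), percent of
#' sample (nearest integer) and the branching rule, with the yes branch
#' printed first (left). DOT renders encode the node mean as a light-to-dark
#' fill ramp and can be drawn with any Graphviz tool.
#'
#' @param tree A `vt_tree`.
#' @param format `"text"` or `"dot"`.
#' @return A character vector of lines (invisibly printable with `cat`).
#' @export
render_tree <- function(tree, format = c("text", "dot")) {
  format <- match.arg(format)
  if (format == "text") return(render_tree_text(tree))
  render_tree_dot(tree)
}

node_label <- function(nd) {
  sprintf("mean_z=%.3f (%d%%) n=%d", nd$mean_z, round(100 * nd$frac), nd$n)
}

split_label <- function(nd) {
  set <- c(as.character(nd$yes_codes), if (nd$yes_missing) "missing")
  paste0(nd$var, " in {", paste(set, collapse = ","), "}?")
}

render_tree_text <- function(tree) {
  out <- character(0)
  walk <- function(id, indent, branch) {
    nd <- tree$nodes[[id]]
    line <- paste0(strrep("  ", indent),
                   if (nzchar(branch)) paste0("[", branch, "] ") else "",
                   node_label(nd),
                   if (length(nd$children)) paste0(" | split: ", split_label(nd)) else "")
    out <<- c(out, line)
    if (length(nd$children)) {
      walk(nd$children[1], indent + 1L, "yes")
      walk(nd$children[2], indent + 1L, "no")
    }
  }
  walk(1L, 0L, "")
  out
}

render_tree_dot <- function(tree) {
  zs <- vapply(tree$nodes, `[[`, 0, "mean_z")
  rng <- range(zs)
  shade <- function(zv) {
    f <- if (diff(rng) > 0) (zv - rng[1]) / diff(rng) else 0.5
    g <- as.integer(round(235 - f * 150))  # light -> dark with mean_z
    sprintf("#%02x%02x%02x", g, g, 255L)
  }
  lines <- c("digraph difference_tree {",
             "  node [shape=box, style=filled, fontname=\"Helvetica\"];")
  for (nd in tree$nodes) {
    lbl <- paste0(node_label(nd),
                  if (length(nd$children)) paste0("\\n", split_label(nd)) else "")
    lines <- c(lines, sprintf("  n%d [label=\"%s\", fillcolor=\"%s\"];",
                              nd$id, lbl, shade(nd$mean_z)))
  }
  for (nd in tree$nodes) {
    if (length(nd$children)) {
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"yes\"];", nd$id, nd$children[1]),
                 sprintf("  n%d -> n%d [label=\"no\"];", nd$id, nd$children[2]))
    }
  }
  c(lines, "}")
}

#' @export
print.vt_tree <- function(x, ...) {
  cat("<vt_tree>", length(x$nodes), "nodes, n =", x$n, "\n")
  cat(render_tree_text(x), sep = "\n")
  invisible(x)
}
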