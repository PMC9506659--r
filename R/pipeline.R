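#' Run the full two-stage disparity analysis
#'
#' Orchestrates, per disparity contrast: outcome coding and attrition
#' bookkeeping, the stage-one learner comparison over repeated splits,
#' finalist selection, a refit on the full analysis sample, counterfactual
#' twin prediction, the stage-two difference tree, and subgroup extraction.
#' Contrast failures are isolated: a failing contrast is logged and skipped
#' while the others proceed.
#'
#' @param cohort A `vt_cohort`.
#' @param contrasts Named list of `vt_contrast`s (default: the nine built-in
#'   disparity contrasts).
#' @param coding A `vt_outcome_coding`.
#' @param learners Named list of `vt_learner_spec`s.
#' @param iterations Train/test iterations per learner.
#' @param frac Training fraction.
#' @param seed Base seed for splits, fits and balancing.
#' @param smote Balance each training split with [smote_balance()].
#' @param z_mode `"refit"` (default): twin differences come from one final
#'   model refit on the full analysis sample. `"average"`: twin predictions
#'   are averaged over the per-iteration models (no refit; no importance
#'   table).
#' @param params Second-stage [tree_params()].
#' @param min_frac Reporting threshold for subgroups (fraction of sample).
#' @param output_dir If given, the report is also written there as delimited
#'   tables and tree renders via [write_report()].
#' @return A `vt_report`: `descriptives`, per-contrast results
#'   (`selection`, `eval`, `importance`, `twins_summary`, `tree`,
#'   `subgroups`, `attrition`), skipped contrasts, and the run configuration.
#' @export
run_full_analysis <- function(cohort,
                              contrasts = builtin_contrasts(),
                              coding = outcome_coding("default", codebook = cohort$codebook),
                              learners = default_learner_roster(),
                              iterations = 10, frac = 0.7, seed = 1,
                              smote = FALSE,
                              z_mode = c("refit", "average"),
                              params = tree_params(),
                              min_frac = 0.01,
                              output_dir = NULL) {
  z_mode <- match.arg(z_mode)
  stopifnot(inherits(cohort, "vt_cohort"))
  vt_log("descriptives over ", n_records(cohort), " records")
  descriptives <- describe_cohort(cohort, coding)
  y_all <- code_outcome(cohort, coding)
  results <- list()
  skipped <- list()
  for (cname in names(contrasts)) {
    contrast <- contrasts[[cname]]
    res <- tryCatch(
      run_one_contrast(cohort, contrast, y_all, learners, iterations, frac,
                       seed, smote, z_mode, params, min_frac),
      error = function(e) e, warning = function(w) w
    )
    if (inherits(res, "condition")) {
      vt_log("contrast ", cname, " skipped: ", conditionMessage(res))
      skipped[[cname]] <- conditionMessage(res)
    } else {
      results[[cname]] <- res
    }
  }
  report <- structure(
    list(descriptives = descriptives, contrasts = results, skipped = skipped,
         config = list(coding = coding$name, learners = names(learners),
                       iterations = iterations, frac = frac, seed = seed,
                       smote = smote, z_mode = z_mode, params = unclass(params),
                       min_frac = min_frac, n_records = n_records(cohort),
                       provenance = cohort$provenance)),
    class = "vt_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

run_one_contrast <- function(cohort, contrast, y_all, learners, iterations,
                             frac, seed, smote, z_mode, params, min_frac) {
  absent <- setdiff(names(contrast$predicate), names(cohort$data))
  if (length(absent)) {
    warning("variable(s) not in cohort: ", paste(absent, collapse = ", "),
            call. = FALSE)
  }
  keep <- !is.na(y_all)
  n_excluded_outcome <- sum(!keep)
  sub <- cohort
  sub$data <- cohort$data[keep, , drop = FALSE]
  y <- y_all[keep]
  design1 <- build_design(sub, contrast, stage = "one")
  design2 <- build_design(sub, contrast, stage = "two")
  y1 <- y[design1$rows]
  vt_log(contrast$name, ": n = ", nrow(design1$x),
         " (outcome-excluded ", n_excluded_outcome,
         ", missing-indicator ", design1$n_dropped, ")")
  eval <- compare_learners(design1, y1, learners, iterations = iterations,
                           frac = frac, seed = seed, smote = smote)
  winner <- select_model(eval)
  vt_log(contrast$name, ": selected ", winner)
  importance <- NULL
  if (z_mode == "refit") {
    xtr <- design1$x; ytr <- y1
    if (smote) {
      bal <- smote_balance(xtr, ytr, seed = seed, variables = design1$variables)
      xtr <- bal$x; ytr <- bal$y
    }
    final <- fit_first_stage(xtr, ytr, learners[[winner]], seed = seed)
    final$feature_names <- colnames(design1$x)
    twins <- predict_twins(final, design1)
    importance <- scaled_importance(final, design1, outcome = y1, seed = seed)
  } else {
    acc1 <- acc0 <- rep(0, nrow(design1$x))
    for (it in seq_len(iterations)) {
      sp <- split_train_test(nrow(design1$x), frac = frac, seed = seed + it - 1L)
      xtr <- design1$x[sp$train, , drop = FALSE]; ytr <- y1[sp$train]
      if (smote) {
        bal <- smote_balance(xtr, ytr, seed = seed + it - 1L,
                             variables = design1$variables)
        xtr <- bal$x; ytr <- bal$y
      }
      m <- fit_first_stage(xtr, ytr, learners[[winner]], seed = seed + it - 1L)
      m$feature_names <- colnames(design1$x)
      tw <- predict_twins(m, design1)
      acc1 <- acc1 + tw$p1; acc0 <- acc0 + tw$p0
    }
    twins <- data.frame(p1 = acc1 / iterations, p0 = acc0 / iterations)
    twins$z <- twins$p1 - twins$p0
    attr(twins, "rows") <- design1$rows
    class(twins) <- c("vt_twins", "data.frame")
  }
  tree <- fit_difference_tree(twins$z, design2, params)
  subgroups <- extract_subgroups(tree, min_frac)
  list(
    contrast = contrast$name,
    selection = list(winner = as.character(winner),
                     summary = attr(winner, "summary")),
    eval = eval,
    importance = importance,
    twins_summary = c(mean = mean(twins$z), sd = stats::sd(twins$z),
                      stats::quantile(twins$z, c(0.05, 0.25, 0.5, 0.75, 0.95))),
    twins = twins,
    tree = tree,
    subgroups = subgroups,
    attrition = c(n_input = length(y_all),
                  n_excluded_outcome = n_excluded_outcome,
                  n_missing_indicator = design1$n_dropped,
                  n_analysis = nrow(design1$x))
  )
}

#' SMOTE robustness run
#'
#' Runs the analysis twice — unbalanced and with SMOTE applied to every
#' training split — and reports side-by-side per-learner metric deltas
#' (SMOTE minus unbalanced).
#'
#' @inheritParams run_full_analysis
#' @return A list with `base` and `smote` reports and per-contrast `deltas`.
#' @export
run_robustness_smote <- function(cohort, contrasts = builtin_contrasts(), ...) {
  base <- run_full_analysis(cohort, contrasts, smote = FALSE, ...)
  bal <- run_full_analysis(cohort, contrasts, smote = TRUE, ...)
  deltas <- list()
  for (cname in intersect(names(base$contrasts), names(bal$contrasts))) {
    sb <- summarize_eval(base$contrasts[[cname]]$eval)
    ss <- summarize_eval(bal$contrasts[[cname]]$eval)
    metrics <- c("accuracy", "auc", "precision", "recall", "f1")
    d <- ss[, metrics] - sb[, metrics]
    deltas[[cname]] <- cbind(learner = sb$learner, d)
  }
  list(base = base, smote = bal, deltas = deltas)
}

#' Planned-discharge outcome robustness run
#'
#' Re-runs the analysis under the alternate coding (completed = 1,
#' dropped-out/terminated = 0, all other discharge reasons excluded) and
#' reports the number of dropped records per discharge reason.
#'
#' @inheritParams run_full_analysis
#' @return A `vt_report` with an extra `dropped_by_reason` table.
#' @export
run_robustness_outcome <- function(cohort, contrasts = builtin_contrasts(), ...) {
  coding <- outcome_coding("planned_discharge_robustness",
                           codebook = cohort$codebook)
  report <- run_full_analysis(cohort, contrasts, coding = coding, ...)
  reason <- cohort$data[["REASON"]]
  dropped <- reason[reason %in% coding$dropped_codes]
  cats <- cohort$codebook$variables[["REASON"]]$categories
  tab <- table(factor(dropped, levels = coding$dropped_codes))
  report$dropped_by_reason <- data.frame(
    code = as.integer(names(tab)),
    label = unname(cats[names(tab)]),
    n_dropped = as.integer(tab)
  )
  report
}

#' Write an analysis report to disk
#'
#' One directory per contrast with the metrics table, selection summary,
#' importance table, subgroup tables and tree renders (text and DOT), plus
#' the cohort descriptives and the effective run configuration at the top
#' level. Everything is a plain-text format.
#'
#' @param report A `vt_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(format_descriptives(report$descriptives),
                   file.path(dir, "descriptives.csv"), row.names = FALSE)
  jsonlite::write_json(report$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (cname in names(report$contrasts)) {
    res <- report$contrasts[[cname]]
    cdir <- file.path(dir, cname)
    dir.create(cdir, showWarnings = FALSE)
    utils::write.csv(as.data.frame(res$eval), file.path(cdir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(res$selection$summary, file.path(cdir, "selection.csv"),
                     row.names = FALSE)
    if (!is.null(res$importance)) {
      utils::write.csv(res$importance, file.path(cdir, "importance.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(res$subgroups$subgroups, file.path(cdir, "subgroups.csv"),
                     row.names = FALSE)
    utils::write.csv(res$subgroups$low_support,
                     file.path(cdir, "subgroups_low_support.csv"),
                     row.names = FALSE)
    writeLines(render_tree(res$tree, "text"), file.path(cdir, "tree.txt"))
    writeLines(render_tree(res$tree, "dot"), file.path(cdir, "tree.dot"))
    writeLines(paste(names(res$attrition), res$attrition, sep = "="),
               file.path(cdir, "attrition.txt"))
  }
  if (length(report$skipped)) {
    writeLines(paste(names(report$skipped), unlist(report$skipped), sep = ": "),
               file.path(dir, "skipped.txt"))
  }
  invisible(dir)
}

#' @export
print.vt_report <- function(x, ...) {
  cat("<vt_report>", length(x$contrasts), "contrast(s) analysed,",
      length(x$skipped), "skipped; coding:", x$config$coding, "\n")
  for (cname in names(x$contrasts)) {
    res <- x$contrasts[[cname]]
    top <- res$subgroups$subgroups[1, ]
    cat(sprintf("  %s: finalist %s; top subgroup %+0.3f (%d%% of sample) %s\n",
                cname, res$selection$winner, top$mean_z,
                round(100 * top$frac), top$rule))
  }
  invisible(x)
}
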