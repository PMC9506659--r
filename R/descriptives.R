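#' Outcome codings for the discharge-reason variable
#'
#' The completion outcome is derived from the seven-category discharge reason
#' (`REASON`). Under the default coding, "treatment completed" is a success
#' (`1`) and the six other reasons (dropped out, terminated by facility,
#' transferred, incarcerated, death, other) are failures (`0`). Under the
#' planned-discharge robustness coding, only dropped-out and
#' facility-terminated discharges are failures and all other non-completion
#' reasons are excluded from analysis.
#'
#' @param name `"default"` or `"planned_discharge_robustness"`, or `"custom"`
#'   together with explicit code sets.
#' @param success_codes,failure_codes,dropped_codes Integer `REASON` code sets
#'   for a custom coding; must be pairwise disjoint and cover all `REASON`
#'   categories.
#' @param codebook Codebook used to check coverage.
#' @return A `vt_outcome_coding`.
#' @export
outcome_coding <- function(name = c("default", "planned_discharge_robustness", "custom"),
                           success_codes = NULL, failure_codes = NULL,
                           dropped_codes = NULL, codebook = load_codebook()) {
  name <- match.arg(name)
  reason_codes <- codebook$variables[["REASON"]]$codes
  if (name == "default") {
    success_codes <- 1L; failure_codes <- setdiff(reason_codes, 1L); dropped_codes <- integer()
  } else if (name == "planned_discharge_robustness") {
    success_codes <- 1L; failure_codes <- c(2L, 3L)
    dropped_codes <- setdiff(reason_codes, c(1L, 2L, 3L))
  } else {
    success_codes <- as.integer(success_codes)
    failure_codes <- as.integer(failure_codes)
    dropped_codes <- as.integer(dropped_codes %||% integer())
  }
  all3 <- c(success_codes, failure_codes, dropped_codes)
  if (anyDuplicated(all3)) {
    stop("outcome coding sets are not pairwise disjoint", call. = FALSE)
  }
  if (!setequal(all3, reason_codes)) {
    stop("outcome coding does not cover all REASON categories", call. = FALSE)
  }
  structure(
    list(name = name, success_codes = success_codes,
         failure_codes = failure_codes, dropped_codes = dropped_codes),
    class = "vt_outcome_coding"
  )
}

#' Code the binary completion outcome
#'
#' Maps each record's discharge reason to `1` (success), `0` (failure), or
#' `NA` (excluded from analysis: a dropped reason under the coding, or a
#' missing reason).
#'
#' @param x A `vt_cohort` or an integer vector of `REASON` codes.
#' @param coding A `vt_outcome_coding`.
#' @return Integer vector of `1`/`0`/`NA`, one per record.
#' @export
code_outcome <- function(x, coding = outcome_coding("default")) {
  reason <- if (inherits(x, "vt_cohort")) x$data[["REASON"]] else as.integer(x)
  if (is.null(reason)) stop("cohort has no REASON variable", call. = FALSE)
  out <- rep(NA_integer_, length(reason))
  out[reason %in% coding$success_codes] <- 1L
  out[reason %in% coding$failure_codes] <- 0L
  out
}

#' Cohort descriptives by completion stratum
#'
#' Recreates the published style of cohort description: per variable and
#' category, frequency and percentage in the full sample and in the
#' treatment-completed and not-completed strata. Percentages are computed over
#' non-missing denominators per variable and stratum and kept unrounded;
#' round to one decimal for display (see [format_descriptives()]).
#' The "not completed" stratum is outcome `0` under the coding, so records the
#' coding excludes contribute only to the full-sample columns.
#'
#' @param cohort A `vt_cohort`.
#' @param coding A `vt_outcome_coding`.
#' @return A data frame (`vt_descriptives`) with columns `variable`, `code`,
#'   `label`, `freq_full`, `pct_full`, `freq_completed`, `pct_completed`,
#'   `freq_not_completed`, `pct_not_completed`.
#' @export
describe_cohort <- function(cohort, coding = outcome_coding("default", codebook = cohort$codebook)) {
  y <- code_outcome(cohort, coding)
  strata <- list(full = rep(TRUE, nrow(cohort$data)),
                 completed = !is.na(y) & y == 1L,
                 not_completed = !is.na(y) & y == 0L)
  rows <- list()
  for (vn in names(cohort$data)) {
    vdef <- cohort$codebook$variables[[vn]]
    x <- cohort$data[[vn]]
    rec <- data.frame(variable = vn, code = vdef$codes,
                      label = unname(vdef$categories))
    for (s in names(strata)) {
      xs <- x[strata[[s]]]
      f <- vapply(vdef$codes, function(cd) sum(xs == cd, na.rm = TRUE), 0L)
      den <- sum(f)
      rec[[paste0("freq_", s)]] <- f
      rec[[paste0("pct_", s)]] <- if (den > 0) 100 * f / den else 0
    }
    rows[[vn]] <- rec
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("vt_descriptives", "data.frame")
  out
}

#' Round a descriptives table for display
#'
#' @param x A `vt_descriptives` table.
#' @param digits Decimal places for percentages (the published table prints 1).
#' @return A plain data frame with rounded percentage columns.
#' @export
format_descriptives <- function(x, digits = 1) {
  out <- as.data.frame(x)
  for (cn in grep("^pct_", names(out), value = TRUE)) {
    out[[cn]] <- round(out[[cn]], digits)
  }
  out
}

#' Packaged cohort-description count fixture
#'
#' Published per-category frequencies and printed percentages for the
#' 2017-2019 TEDS-D analysis sample (649,479 discharges), by completion
#' stratum. Used as the default marginals of the synthetic generator and to
#' check that recomputed shares agree with the printed percentages to printed
#' rounding.
#'
#' @return A data frame with columns `variable`, `code`, `label`,
#'   `freq_full`, `pct_full`, `freq_completed`, `pct_completed`,
#'   `freq_not_completed`, `pct_not_completed`.
#' @export
table1_counts <- function() {
  path <- system.file("extdata", "table1_counts.csv", package = "vtdisparity")
  utils::read.csv(path, check.names = TRUE)
}

#' Recompute stratum shares from a count table
#'
#' Computes percentages from the frequency columns of a count fixture (per
#' variable and stratum, over that variable's column sum), for comparison with
#' the printed percentages.
#'
#' @param counts A data frame as returned by [table1_counts()].
#' @return The input with `pct_full_recomputed`, `pct_completed_recomputed`,
#'   and `pct_not_completed_recomputed` columns appended.
#' @export
recompute_shares <- function(counts = table1_counts()) {
  for (s in c("full", "completed", "not_completed")) {
    f <- counts[[paste0("freq_", s)]]
    den <- stats::ave(f, counts$variable, FUN = sum)
    counts[[paste0("pct_", s, "_recomputed")]] <- ifelse(den > 0, 100 * f / den, 0)
  }
  counts
}
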