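#' Define a binary disparity contrast
#'
#' A contrast derives the binary attribute `T` analysed by the virtual-twins
#' procedure: `T = 1` for records satisfying the predicate (the focal group),
#' `0` for records where the predicate is evaluable and false, and missing
#' when any source variable is missing. The predicate is a conjunction of
#' variable-in-category-set clauses, e.g. white non-Hispanic is
#' `RACE = White AND ETHNIC = Not of Hispanic or Latino Origin`.
#'
#' @param name Identifier for the contrast.
#' @param predicate Named list mapping variable names to integer category-code
#'   sets; a record is focal when every listed variable's code is in its set.
#' @param source_variables Variables the predicate consumes (defaults to the
#'   predicate's variables).
#' @param masked_variables Variables excluded from the second-stage design
#'   (and, by default, from the first stage alongside the sources); must
#'   contain the source variables.
#' @return A `vt_contrast`.
#' @export
disparity_contrast <- function(name, predicate,
                               source_variables = names(predicate),
                               masked_variables = source_variables) {
  if (!all(source_variables %in% masked_variables)) {
    stop("masked_variables must contain all source_variables", call. = FALSE)
  }
  structure(
    list(name = name, predicate = predicate,
         source_variables = source_variables,
         masked_variables = masked_variables),
    class = "vt_contrast"
  )
}

#' @export
print.vt_contrast <- function(x, ...) {
  clauses <- vapply(names(x$predicate), function(vn) {
    paste0(vn, " in {", paste(x$predicate[[vn]], collapse = ","), "}")
  }, "")
  cat("<vt_contrast>", x$name, ":", paste(clauses, collapse = " AND "), "\n")
  invisible(x)
}

#' The nine built-in disparity contrasts
#'
#' Focal groups: white non-Hispanic; income from wages/salary; no
#' co-occurring mental health disorder; male; no health insurance; veteran;
#' under 35 at admission; primary substance alcohol; primary substance opioid
#' (heroin, non-prescription methadone, or other opiates and synthetics).
#' The health-insurance contrast uses the optional `HLTHINS` variable;
#' cohorts lacking it skip that contrast with a warning at run time.
#'
#' @return Named list of `vt_contrast` objects.
#' @export
builtin_contrasts <- function() {
  cs <- list(
    disparity_contrast("white_non_hispanic",
                       list(RACE = 5L, ETHNIC = 4L)),
    disparity_contrast("wage_income", list(PRIMINC = 1L)),
    disparity_contrast("no_cooccurring_disorder", list(PSYPROB = 2L)),
    disparity_contrast("male", list(GENDER = 1L)),
    disparity_contrast("no_insurance", list(HLTHINS = 4L)),
    disparity_contrast("veteran", list(VET = 1L)),
    disparity_contrast("age_under_35", list(AGE = 1:6)),
    disparity_contrast("alcohol_primary", list(SUB1 = 2L)),
    disparity_contrast("opioid_primary", list(SUB1 = c(5L, 6L, 7L)))
  )
  stats::setNames(cs, vapply(cs, `[[`, "", "name"))
}

#' Derive the binary indicator of a contrast
#'
#' @param cohort A `vt_cohort`.
#' @param contrast A `vt_contrast`.
#' @return Integer vector per record: `1` (focal), `0` (comparison), or `NA`
#'   when any source variable is missing.
#' @export
derive_indicator <- function(cohort, contrast) {
  data <- cohort$data
  unknown <- setdiff(names(contrast$predicate), names(data))
  if (length(unknown)) {
    stop("contrast ", contrast$name, " references variable(s) absent from cohort: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ind <- rep(1L, nrow(data))
  anymiss <- rep(FALSE, nrow(data))
  for (vn in names(contrast$predicate)) {
    x <- data[[vn]]
    anymiss <- anymiss | is.na(x)
    ind <- ind & (x %in% contrast$predicate[[vn]])
  }
  ind <- as.integer(ind)
  ind[anymiss] <- NA_integer_
  ind
}

#' Build the one-hot covariate design for one analysis stage
#'
#' Expands every retained cohort variable into indicator columns (one per
#' category plus one per-variable missing indicator, so each variable's block
#' sums to 1 for every record). The stage-one design appends the derived
#' indicator column `T` (named after the contrast) and drops the contrast's
#' raw source variables, so the flexible model cannot reconstruct `T` from
#' them and make the counterfactual flip inert. The stage-two design drops
#' all masked variables and carries no `T` column. The outcome variable
#' `REASON` is never a covariate. Records whose indicator is missing are
#' dropped and counted.
#'
#' @param cohort A `vt_cohort`.
#' @param contrast A `vt_contrast`, or `NULL` for a plain design with no
#'   indicator (all variables retained).
#' @param stage `"one"` or `"two"`.
#' @param include_sources_stage_one Keep the raw source variables in the
#'   stage-one design alongside `T` (off by default; see Details in the
#'   package vignette).
#' @return A `vt_design`: `$x` numeric indicator matrix, `$data` the retained
#'   records' raw codes for split-search, `$rows` the cohort row indices
#'   retained, `$variables` per-variable column metadata, `$t_col` the name
#'   of the indicator column (stage one), `$n_dropped` records dropped for a
#'   missing indicator.
#' @export
build_design <- function(cohort, contrast = NULL, stage = c("one", "two"),
                         include_sources_stage_one = FALSE) {
  stage <- match.arg(stage)
  data <- cohort$data
  drop_vars <- "REASON"
  t_col <- NULL
  ind <- NULL
  if (!is.null(contrast)) {
    ind <- derive_indicator(cohort, contrast)
    if (stage == "one") {
      if (!include_sources_stage_one) {
        drop_vars <- c(drop_vars, contrast$source_variables)
      }
      t_col <- contrast$name
    } else {
      drop_vars <- c(drop_vars, contrast$masked_variables)
    }
  }
  keep_vars <- setdiff(names(data), drop_vars)
  if (!length(keep_vars)) stop("empty design after masking", call. = FALSE)
  rows <- seq_len(nrow(data))
  n_dropped <- 0L
  if (!is.null(ind)) {
    rows <- which(!is.na(ind))
    n_dropped <- nrow(data) - length(rows)
    if (!length(rows)) stop("all records have a missing indicator", call. = FALSE)
  }
  sub <- data[rows, keep_vars, drop = FALSE]
  blocks <- list()
  variables <- list()
  for (vn in keep_vars) {
    vdef <- cohort$codebook$variables[[vn]]
    x <- sub[[vn]]
    cols <- c(paste0(vn, "=", vdef$codes), paste0(vn, "=missing"))
    m <- matrix(0, nrow = nrow(sub), ncol = length(cols),
                dimnames = list(NULL, cols))
    idx <- match(x, vdef$codes)
    idx[is.na(idx)] <- length(cols)  # missing indicator column
    m[cbind(seq_len(nrow(sub)), idx)] <- 1
    blocks[[vn]] <- m
    variables[[vn]] <- list(columns = cols, codes = vdef$codes)
  }
  x <- do.call(cbind, blocks)
  if (!is.null(t_col)) {
    x <- cbind(x, matrix(ind[rows], ncol = 1, dimnames = list(NULL, t_col)))
    variables[[t_col]] <- list(columns = t_col, codes = c(0L, 1L))
  }
  structure(
    list(x = x, data = sub, rows = rows, variables = variables,
         t_col = t_col, stage = stage,
         contrast = if (is.null(contrast)) NULL else contrast$name,
         n_dropped = n_dropped),
    class = "vt_design"
  )
}

#' @export
print.vt_design <- function(x, ...) {
  cat("<vt_design> stage", x$stage, ":", nrow(x$x), "records x", ncol(x$x),
      "columns (", length(x$variables), "variables;", x$n_dropped,
      "dropped for missing indicator )\n")
  invisible(x)
}
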