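#' Read a coded discharge cohort
#'
#' Reads a comma-separated discharge table (UTF-8, header of codebook variable
#' abbreviations, integer category codes) and validates every cell against the
#' codebook. Codes listed in a variable's `missing_codes` and empty cells are
#' normalized to the single internal missing marker (`NA`), so downstream code
#' never sees a source-specific missing code such as TEDS-D's `-9`. Each row is
#' one discharge episode, not one person.
#'
#' @param path Path to a CSV file.
#' @param codebook A `vt_codebook`; defaults to the packaged TEDS-D codebook.
#' @param provenance Free-text source tag stored on the cohort.
#' @return A `vt_cohort`: records (`$data`, integer codes with `NA` for
#'   missing), the codebook, and the provenance tag.
#' @export
read_cohort <- function(path, codebook = load_codebook(), provenance = path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!nrow(raw)) stop("cohort file has no records: ", path, call. = FALSE)
  unknown <- setdiff(names(raw), names(codebook$variables))
  if (length(unknown)) {
    stop("unknown variable(s) in header: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  required <- names(codebook$variables)[!vapply(codebook$variables, `[[`, TRUE, "optional")]
  absent <- setdiff(required, names(raw))
  if (length(absent)) {
    stop("required variable(s) absent from file: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(lapply(names(raw), function(vn) {
    decode_column(raw[[vn]], codebook$variables[[vn]], vn)
  }), optional = TRUE)
  names(data) <- names(raw)
  as_cohort(data, codebook, provenance)
}

decode_column <- function(cells, vdef, vn) {
  cells <- trimws(cells)
  out <- suppressWarnings(as.integer(cells))
  empty <- !nzchar(cells)
  bad_parse <- is.na(out) & !empty
  if (any(bad_parse)) {
    stop("non-integer code in column ", vn, " at row ", which(bad_parse)[1],
         ": '", cells[which(bad_parse)[1]], "'", call. = FALSE)
  }
  out[empty | out %in% vdef$missing_codes] <- NA_integer_
  invalid <- !is.na(out) & !out %in% vdef$codes
  if (any(invalid)) {
    stop("invalid code in column ", vn, " at row ", which(invalid)[1],
         ": ", out[which(invalid)[1]], call. = FALSE)
  }
  out
}

# Internal constructor; validates all records against the codebook.
as_cohort <- function(data, codebook, provenance = "in-memory") {
  stopifnot(is.data.frame(data))
  if (!nrow(data)) stop("a cohort must contain at least one record", call. = FALSE)
  for (vn in names(data)) {
    vdef <- codebook$variables[[vn]]
    if (is.null(vdef)) stop("unknown variable: ", vn, call. = FALSE)
    x <- data[[vn]]
    bad <- !is.na(x) & !x %in% vdef$codes
    if (any(bad)) {
      stop("invalid code for variable ", vn, ": ", x[which(bad)[1]],
           " (row ", which(bad)[1], ")", call. = FALSE)
    }
    data[[vn]] <- as.integer(x)
  }
  structure(
    list(data = data, codebook = codebook, provenance = provenance),
    class = "vt_cohort"
  )
}

#' Write a cohort back to the delimited dialect
#'
#' Missing values are written as the variable's first declared missing code
#' (`-9` in the TEDS-D dialect), so a read/write cycle is the identity on
#' codes.
#'
#' @param cohort A `vt_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort$data
  for (vn in names(out)) {
    mc <- cohort$codebook$variables[[vn]]$missing_codes
    if (length(mc) && anyNA(out[[vn]])) {
      out[[vn]][is.na(out[[vn]])] <- mc[1]
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.vt_cohort <- function(x, ...) {
  cat("<vt_cohort>", nrow(x$data), "discharge records,",
      ncol(x$data), "variables (", x$provenance, ")\n")
  invisible(x)
}

#' Number of discharge records in a cohort
#' @param cohort A `vt_cohort`.
#' @export
n_records <- function(cohort) nrow(cohort$data)

#' Per-variable missingness report
#'
#' @param cohort A `vt_cohort`.
#' @return A data frame with one row per cohort variable: `variable`,
#'   `n_missing`, and `fraction_missing` (missing count over record count).
#' @examples
#' cb <- load_codebook()
#' @export
missingness_report <- function(cohort) {
  n <- nrow(cohort$data)
  nm <- vapply(cohort$data, function(x) sum(is.na(x)), 0L)
  data.frame(
    variable = names(cohort$data),
    n_missing = unname(nm),
    fraction_missing = unname(nm) / n,
    row.names = NULL
  )
}
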