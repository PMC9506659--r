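#' Load a codebook specification
#'
#' A codebook defines the coded-categorical data model for a discharge table:
#' for each variable, its short uppercase name (e.g. `REASON`, `SERVICES`,
#' `PSYPROB`), a label, the ordered mapping of integer category codes to
#' labels, the set of source codes treated as missing (TEDS-D public-use files
#' use `-9`), and whether the variable may be absent from a data file
#' (`optional`). The file format is YAML with a top-level `variables` list;
#' see the packaged default at
#' `system.file("extdata", "tedsd_codebook.yaml", package = "vtdisparity")`.
#'
#' @param path Path to a YAML codebook file. Defaults to the packaged TEDS-D
#'   2017-2019 codebook, which covers all variables and categories of the
#'   published cohort description plus the optional discharge-service and
#'   health-insurance variables.
#' @return A `vt_codebook` object.
#' @examples
#' cb <- load_codebook()
#' length(codebook_categories(cb, "REASON")) # 7 discharge reasons
#' @export
load_codebook <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tedsd_codebook.yaml", package = "vtdisparity")
  }
  if (!file.exists(path)) stop("codebook file not found: ", path, call. = FALSE)
  spec <- yaml::read_yaml(path)
  if (is.null(spec$variables) || !length(spec$variables)) {
    stop("codebook spec has no `variables` entry", call. = FALSE)
  }
  vars <- lapply(spec$variables, function(v) {
    if (is.null(v$name)) stop("codebook variable without a `name`", call. = FALSE)
    codes <- suppressWarnings(as.integer(names(v$categories)))
    if (anyNA(codes)) {
      stop("non-integer category code under variable ", v$name, call. = FALSE)
    }
    list(
      name = as.character(v$name),
      label = as.character(v$label %||% v$name),
      optional = isTRUE(v$optional),
      missing_codes = as.integer(unlist(v$missing_codes %||% integer())),
      codes = codes,
      categories = stats::setNames(vapply(v$categories, as.character, ""), codes)
    )
  })
  names(vars) <- vapply(vars, `[[`, "", "name")
  cb <- structure(
    list(name = as.character(spec$name %||% basename(path)), variables = vars),
    class = "vt_codebook"
  )
  validate_codebook(cb)
  cb
}

validate_codebook <- function(cb) {
  nm <- names(cb$variables)
  if (anyDuplicated(nm)) {
    stop("duplicate variable name in codebook: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  for (v in cb$variables) {
    if (anyDuplicated(v$codes)) {
      stop("duplicate category code under variable ", v$name, ": ",
           paste(unique(v$codes[duplicated(v$codes)]), collapse = ", "),
           call. = FALSE)
    }
    if (length(intersect(v$missing_codes, v$codes))) {
      stop("missing code overlaps category codes for variable ", v$name,
           call. = FALSE)
    }
    if (!length(v$codes)) stop("variable ", v$name, " has no categories", call. = FALSE)
  }
  invisible(cb)
}

#' Construct a codebook in code
#'
#' Programmatic counterpart of [load_codebook()], used to build small
#' codebooks in tests and to extend the packaged default (e.g. with a
#' synthetic binary attribute).
#'
#' @param variables A list of variable definitions; each element is a list
#'   with `name`, `categories` (named vector, names are integer codes),
#'   and optionally `label`, `missing_codes`, `optional`.
#' @param name Free-text codebook name.
#' @return A `vt_codebook`.
#' @export
codebook <- function(variables, name = "ad-hoc") {
  vars <- lapply(variables, function(v) {
    codes <- suppressWarnings(as.integer(names(v$categories)))
    if (anyNA(codes)) stop("category codes must be integers (as names)", call. = FALSE)
    list(
      name = as.character(v$name),
      label = as.character(v$label %||% v$name),
      optional = isTRUE(v$optional),
      missing_codes = as.integer(v$missing_codes %||% -9L),
      codes = codes,
      categories = stats::setNames(as.character(v$categories), codes)
    )
  })
  names(vars) <- vapply(vars, `[[`, "", "name")
  cb <- structure(list(name = name, variables = vars), class = "vt_codebook")
  validate_codebook(cb)
  cb
}

#' @export
print.vt_codebook <- function(x, ...) {
  cat("<vt_codebook>", x$name, "\n")
  cat(" ", length(x$variables), "variables:",
      paste(utils::head(names(x$variables), 8), collapse = ", "),
      if (length(x$variables) > 8) "..." else "", "\n")
  invisible(x)
}

#' Codebook accessors
#'
#' @param cb A `vt_codebook`.
#' @param variable Variable name.
#' @return `codebook_variables()` returns the variable names;
#'   `codebook_categories()` the named code-to-label mapping of one variable.
#' @export
codebook_variables <- function(cb) names(cb$variables)

#' @rdname codebook_variables
#' @export
codebook_categories <- function(cb, variable) {
  v <- cb$variables[[variable]]
  if (is.null(v)) stop("unknown variable: ", variable, call. = FALSE)
  v$categories
}

#' Write a codebook to its YAML spec format
#'
#' Serializes a codebook in the same schema [load_codebook()] reads, so
#' generated cohorts can travel with the codebook that validates them.
#'
#' @param cb A `vt_codebook`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  q <- function(s) paste0("\"", gsub("\"", "\\\\\"", s), "\"")
  out <- c(paste0("name: ", cb$name), "variables:")
  for (v in cb$variables) {
    out <- c(out,
             paste0("  - name: ", v$name),
             paste0("    label: ", q(v$label)),
             paste0("    optional: ", tolower(v$optional)),
             paste0("    missing_codes: [", paste(v$missing_codes, collapse = ", "), "]"),
             "    categories:",
             paste0("      ", v$codes, ": ", q(unname(v$categories))))
  }
  writeLines(out, path)
  invisible(path)
}

# Append a binary attribute variable (used by the synthetic generator).
augment_codebook <- function(cb, name, labels = c(`0` = "Comparison group", `1` = "Focal group")) {
  stopifnot(!name %in% names(cb$variables))
  cb$variables[[name]] <- list(
    name = name, label = paste("Binary attribute", name), optional = FALSE,
    missing_codes = -9L,
    codes = as.integer(names(labels)),
    categories = labels
  )
  validate_codebook(cb)
  cb
}
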