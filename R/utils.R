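#' @keywords internal
"_PACKAGE"

#' Standard logistic function
#'
#' @param eta Numeric vector of log-odds.
#' @return `1 / (1 + exp(-eta))`, vectorized.
#' @export
sigmoid <- function(eta) 1 / (1 + exp(-eta))

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Rank-based AUC (Mann-Whitney); tied scores count 1/2 concordant.
auc_rank <- function(probs, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(probs, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

vt_log <- function(..., verbose = getOption("vtdisparity.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
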