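#' Configure a synthetic TEDS-D-like cohort
#'
#' Defines a generative model for coded categorical discharge cohorts with a
#' known completion process, so the whole two-stage pipeline can be exercised
#' against closed-form ground truth. Covariates are drawn independently from
#' per-variable category marginals (defaulting to the packaged full-sample
#' frequencies), a binary disparity attribute `T` is drawn Bernoulli, and the
#' completion outcome is Bernoulli with log-odds
#' \deqn{\eta(x, T) = \beta_0 + \beta_T T + \sum_v \beta_x[v, x_v] +
#'   \sum_k \gamma_k T \, 1[x \in S_k],}
#' where the \eqn{S_k} are planted subgroups given as predicates (conjunctions
#' of variable-in-category-set clauses). The outcome is written into the
#' cohort as a `REASON` code: successes become "treatment completed" and
#' failures draw a non-completion reason from the published not-completed
#' reason mix, so both outcome codings behave as on real data.
#'
#' @param n Number of discharge records.
#' @param variables Covariate variables to simulate (codebook names).
#'   Defaults to all non-optional variables of the packaged codebook except
#'   `REASON`, which is generated from the outcome model.
#' @param marginals Named list of category probability vectors (names are
#'   category codes). Defaults to the packaged full-sample frequencies;
#'   for the optional discharge-service variable `SERVICES_D`, which the
#'   published table describes only at admission, the admission marginal is
#'   reused.
#' @param treated_attr Name of the binary disparity attribute column
#'   (categories `0`/`1`).
#' @param p_treated `P(T = 1)`.
#' @param beta0 Intercept, log-odds scale.
#' @param beta_T Main effect of `T`, log-odds scale.
#' @param beta_x Named list: variable -> named numeric vector of per-category
#'   log-odds offsets (names are category codes; unlisted categories are 0).
#' @param interactions List of `list(predicate = , gamma = )` planted
#'   subgroup interactions on `T`; each predicate is a named list mapping
#'   variables to integer category-code sets (conjunction across variables).
#' @param missingness Named numeric vector of per-variable MCAR masking
#'   rates in `[0, 1]`; applied by [apply_missingness()].
#' @param codebook Base codebook; the treated attribute is appended to it.
#' @return A `vt_synthetic_config`.
#' @export
synthetic_config <- function(n,
                             variables = NULL,
                             marginals = NULL,
                             treated_attr = "T",
                             p_treated = 0.5,
                             beta0 = 0,
                             beta_T = 0,
                             beta_x = list(),
                             interactions = list(),
                             missingness = numeric(),
                             codebook = load_codebook()) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  optional <- vapply(codebook$variables, `[[`, TRUE, "optional")
  if (is.null(variables)) {
    variables <- setdiff(names(codebook$variables)[!optional], "REASON")
  }
  unknown <- setdiff(variables, names(codebook$variables))
  if (length(unknown)) stop("unknown variable(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(marginals)) marginals <- default_marginals()
  marginals <- marginals[variables]
  for (vn in variables) {
    m <- marginals[[vn]]
    if (is.null(m)) stop("no marginal available for variable ", vn, call. = FALSE)
    if (!setequal(names(m), as.character(codebook$variables[[vn]]$codes))) {
      stop("marginal categories do not match codebook for ", vn, call. = FALSE)
    }
    if (any(m < 0) || abs(sum(m) - 1) > 1e-9) {
      stop("marginal for ", vn, " must be a probability vector summing to 1", call. = FALSE)
    }
  }
  if (p_treated < 0 || p_treated > 1) stop("`p_treated` must be in [0, 1]", call. = FALSE)
  check_coef_refs(beta_x, interactions, variables, codebook)
  if (length(missingness)) {
    if (any(missingness < 0 | missingness > 1)) {
      stop("missingness rates must be in [0, 1]", call. = FALSE)
    }
    bad <- setdiff(names(missingness), variables)
    if (length(bad)) stop("missingness on unknown variable(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n = as.integer(n), variables = variables, marginals = marginals,
         treated_attr = treated_attr, p_treated = p_treated,
         beta0 = beta0, beta_T = beta_T, beta_x = beta_x,
         interactions = interactions, missingness = missingness,
         codebook = augment_codebook(codebook, treated_attr)),
    class = "vt_synthetic_config"
  )
}

check_coef_refs <- function(beta_x, interactions, variables, codebook) {
  for (vn in names(beta_x)) {
    if (!vn %in% variables) stop("beta_x references unknown variable: ", vn, call. = FALSE)
    bad <- setdiff(names(beta_x[[vn]]), as.character(codebook$variables[[vn]]$codes))
    if (length(bad)) {
      stop("beta_x references unknown category ", bad[1], " of ", vn, call. = FALSE)
    }
  }
  for (it in interactions) {
    if (is.null(it$predicate) || is.null(it$gamma)) {
      stop("each interaction needs `predicate` and `gamma`", call. = FALSE)
    }
    for (vn in names(it$predicate)) {
      if (!vn %in% variables) stop("interaction predicate references unknown variable: ", vn, call. = FALSE)
      bad <- setdiff(it$predicate[[vn]], codebook$variables[[vn]]$codes)
      if (length(bad)) {
        stop("interaction predicate references unknown category ", bad[1], " of ", vn, call. = FALSE)
      }
    }
  }
  invisible(NULL)
}

# Full-sample category frequencies of the packaged count fixture, as marginals.
default_marginals <- function() {
  t1 <- table1_counts()
  out <- lapply(split(t1, t1$variable), function(s) {
    stats::setNames(s$freq_full / sum(s$freq_full), s$code)
  })
  out$SERVICES_D <- out$SERVICES
  out
}

# eta(x, t) for a data frame of covariate codes and scalar/vector t;
# categories without a beta_x coefficient contribute 0
synthetic_eta <- function(data, t, config) {
  eta <- rep(config$beta0, nrow(data)) + config$beta_T * t
  for (vn in names(config$beta_x)) {
    v <- unname(config$beta_x[[vn]][as.character(data[[vn]])])
    v[is.na(v)] <- 0
    eta <- eta + v
  }
  for (it in config$interactions) {
    eta <- eta + it$gamma * t * as.numeric(predicate_members(data, it$predicate))
  }
  eta
}

# Logical membership vector for a predicate (conjunction of var-in-set clauses).
predicate_members <- function(data, predicate) {
  inS <- rep(TRUE, nrow(data))
  for (vn in names(predicate)) {
    inS <- inS & data[[vn]] %in% predicate[[vn]]
  }
  inS
}

#' Closed-form per-record twin difference
#'
#' Ground-truth counterpart of the predicted probability difference: for
#' covariates `x`, returns \eqn{\sigma(\eta(x, 1)) - \sigma(\eta(x, 0))}
#' under the configured outcome model.
#'
#' @param data A data frame of covariate codes (rows = records) or a
#'   `vt_cohort`.
#' @param config A `vt_synthetic_config`.
#' @return Numeric vector of true probability differences in `[-1, 1]`.
#' @export
true_twin_difference <- function(data, config) {
  if (inherits(data, "vt_cohort")) data <- data$data
  sigmoid(synthetic_eta(data, 1, config)) - sigmoid(synthetic_eta(data, 0, config))
}

#' Exact expected twin difference within a subgroup
#'
#' Computes \eqn{E[z_{true} \mid x \in S]} exactly by enumerating the joint
#' distribution of the variables that enter the outcome model or the subgroup
#' predicate (covariates are independent under the generator, so all other
#' variables integrate out).
#'
#' @param config A `vt_synthetic_config`.
#' @param predicate Subgroup predicate (named list of category-code sets);
#'   `NULL` for the whole population.
#' @return A single number: the exact mean true twin difference over the
#'   subgroup.
#' @export
expected_subgroup_z <- function(config, predicate = NULL) {
  active <- union(names(config$beta_x),
                  unlist(lapply(config$interactions, function(it) names(it$predicate))))
  active <- union(active, names(predicate))
  if (!length(active)) {
    return(sigmoid(config$beta0 + config$beta_T) - sigmoid(config$beta0))
  }
  grids <- lapply(active, function(vn) as.integer(names(config$marginals[[vn]])))
  names(grids) <- active
  joint <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  w <- rep(1, nrow(joint))
  for (vn in active) {
    w <- w * unname(config$marginals[[vn]][as.character(joint[[vn]])])
  }
  keep <- if (is.null(predicate)) rep(TRUE, nrow(joint)) else predicate_members(joint, predicate)
  if (!any(keep)) stop("predicate has zero probability under the marginals", call. = FALSE)
  z <- true_twin_difference(joint[keep, , drop = FALSE], config)
  sum(w[keep] * z) / sum(w[keep])
}

#' Sample a synthetic cohort with ground truth
#'
#' @param config A `vt_synthetic_config`.
#' @param seed Integer seed; a fixed seed gives a bit-identical cohort.
#' @return A list with `cohort` (a `vt_cohort` including the treated
#'   attribute and a generated `REASON` column) and `truth` (a data frame of
#'   `p1_true`, `p0_true`, `z_true` per record).
#' @export
sample_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "vt_synthetic_config"))
  with_seed(seed, {
    n <- config$n
    data <- as.data.frame(lapply(config$variables, function(vn) {
      m <- config$marginals[[vn]]
      sample(as.integer(names(m)), n, replace = TRUE, prob = m)
    }), optional = TRUE)
    names(data) <- config$variables
    t_obs <- stats::rbinom(n, 1L, config$p_treated)
    p1 <- sigmoid(synthetic_eta(data, 1, config))
    p0 <- sigmoid(synthetic_eta(data, 0, config))
    p_obs <- ifelse(t_obs == 1L, p1, p0)
    y <- stats::rbinom(n, 1L, p_obs)
    # failure reasons drawn from the published not-completed reason mix
    t1 <- table1_counts()
    fr <- t1[t1$variable == "REASON" & t1$code != 1, ]
    reason <- rep(1L, n)
    nfail <- sum(y == 0L)
    if (nfail > 0) {
      reason[y == 0L] <- sample(fr$code, nfail, replace = TRUE,
                                prob = fr$freq_not_completed / sum(fr$freq_not_completed))
    }
    data$REASON <- reason
    data[[config$treated_attr]] <- t_obs
    cohort <- as_cohort(data, config$codebook, provenance = "synthetic")
    truth <- data.frame(p1_true = p1, p0_true = p0, z_true = p1 - p0)
    list(cohort = cohort, truth = truth)
  })
}

#' Apply MCAR missingness to a cohort
#'
#' Masks each configured variable independently at its configured rate.
#' The discharge reason (`REASON`) is never masked: it carries the outcome.
#'
#' @param cohort A `vt_cohort`.
#' @param rates Named numeric vector of per-variable masking probabilities,
#'   or a `vt_synthetic_config` (its `missingness` field is used).
#' @param seed Integer seed.
#' @return The masked `vt_cohort`.
#' @export
apply_missingness <- function(cohort, rates, seed = 1) {
  if (inherits(rates, "vt_synthetic_config")) rates <- rates$missingness
  if (!length(rates)) return(cohort)
  if (any(rates < 0 | rates > 1)) stop("missingness rates must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    for (vn in names(rates)) {
      if (identical(vn, "REASON")) next
      if (!vn %in% names(cohort$data)) stop("unknown variable: ", vn, call. = FALSE)
      mask <- stats::runif(nrow(cohort$data)) < rates[[vn]]
      cohort$data[[vn]][mask] <- NA_integer_
    }
    cohort
  })
}

#' Write the ground-truth table alongside a cohort
#'
#' @param truth The `truth` data frame from [sample_cohort()].
#' @param path Output CSV path; rows are keyed by record index.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(cbind(record = seq_len(nrow(truth)), truth), path, row.names = FALSE)
  invisible(path)
}
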