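#' Check that a transition matrix is regular
#'
#' A row-stochastic matrix `P` is regular when some power `P^m` has all
#' entries strictly positive; a regular chain has a unique stationary
#' distribution that every starting state vector converges to. Powers
#' are checked up to the Wielandt primitivity bound
#' `(K - 1)^2 + 1`, which is sufficient: a primitive K x K matrix must
#' have a strictly positive power by then.
#'
#' @param P K x K row-stochastic matrix.
#' @param max_power highest power checked (default the Wielandt bound).
#' @return list with `regular` (logical) and `power` (the smallest
#'   certifying `m`, or `NA` if none).
#' @export
is_regular <- function(P, max_power = (nrow(P) - 1L)^2 + 1L) {
  check_transition_matrix(P)
  M <- P
  for (m in seq_len(max(1L, max_power))) {
    if (all(M > 0)) return(list(regular = TRUE, power = m))
    M <- M %*% P
  }
  list(regular = FALSE, power = NA_integer_)
}

check_transition_matrix <- function(P, tol = 1e-8) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop("P must be a square matrix")
  }
  if (any(P < -tol) || any(P > 1 + tol)) stop("P entries must lie in [0, 1]")
  if (any(abs(rowSums(P) - 1) > tol)) stop("rows of P must sum to 1")
  invisible(P)
}

#' Propagate a state vector through the chain
#'
#' The class-prevalence vector after `d` days is
#' `S_d = S_1 P^(d-1)`: one left-multiplication by the transition
#' matrix per elapsed day, with `d = 1` returning the initial vector.
#'
#' @param S1 initial state (probability) vector.
#' @param P transition matrix.
#' @param d day index (>= 1).
#' @return state vector at day `d`.
#' @export
propagate <- function(S1, P, d) {
  if (d < 1) stop("d must be >= 1")
  check_transition_matrix(P)
  s <- matrix(S1, 1L)
  for (i in seq_len(d - 1L)) s <- s %*% P
  stats::setNames(as.vector(s), colnames(P))
}

#' Stationary distribution of a regular transition matrix
#'
#' The unique probability vector `S` with `S P = S`, interpreted as the
#' usual (long-run) prevalence of the latent states. Computed by power
#' iteration from the uniform vector until successive iterates differ
#' by less than `tol` in max-norm, and cross-checked against the left
#' eigenvector of `P` for the unit eigenvalue; disagreement beyond
#' `1e-8` raises a warning.
#'
#' @param P regular transition matrix (checked; non-regular input is an
#'   error, since the limit would depend on the start).
#' @param tol power-iteration max-norm tolerance.
#' @param max_iter iteration cap.
#' @return stationary probability vector.
#' @export
stationary <- function(P, tol = 1e-12, max_iter = 1e6) {
  reg <- is_regular(P)
  if (!reg$regular) {
    stop("transition matrix is not regular (no strictly positive power ",
         "up to the Wielandt bound); the chain has no unique limit")
  }
  K <- nrow(P)
  s <- rep(1 / K, K)
  for (i in seq_len(max_iter)) {
    s_new <- as.vector(s %*% P)
    if (max(abs(s_new - s)) < tol) {
      s <- s_new
      break
    }
    s <- s_new
  }
  s <- s / sum(s)
  ev <- eigen(t(P))
  i1 <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i1])
  v <- v / sum(v)
  if (max(abs(v - s)) > 1e-8) {
    warning("power iteration and eigenvector routes disagree beyond 1e-8")
  }
  stats::setNames(s, colnames(P))
}

# Fast stationary vector via a linear solve (sum-to-one row replacing
# one balance equation); used per subject where thousands of small
# chains are solved.
stationary_solve <- function(P) {
  K <- nrow(P)
  A <- t(diag(K) - P)
  A[K, ] <- 1
  b <- c(rep(0, K - 1L), 1)
  as.vector(solve(A, b))
}

#' Usual prevalence of dietary patterns from a fitted transition model
#'
#' The long-run (stationary) prevalence implied by the fitted
#' day-to-day transitions. In `"individual"` mode (default) each
#' subject's covariate-conditional transition matrix is solved for its
#' stationary vector and the results are averaged over the cohort; in
#' `"aggregate"` mode the stationary vector of the single cohort-level
#' matrix from [aggregate_transition_matrix()] is returned. Both are
#' reported next to the day-1 and day-2 model-based prevalences, whose
#' contrast with the usual prevalence is the point of the method: a
#' single recall day misstates how many people habitually follow each
#' pattern.
#'
#' @param fit `lta_fit` object.
#' @param covariates optional covariate table (defaults to the fitting
#'   cohort).
#' @param mode `"individual"` or `"aggregate"`.
#' @return list with `usual` (the S-infinity vector), `s1`, `s2`
#'   (cohort day-1/day-2 prevalences), `mode`, and in individual mode
#'   `per_subject` (N x K matrix of subject-level stationary vectors).
#' @export
usual_prevalence <- function(fit, covariates = NULL,
                             mode = c("individual", "aggregate")) {
  mode <- match.arg(mode)
  params <- fit$params
  K <- params$K
  X <- if (is.null(covariates)) fit$X else {
    cv <- validate_covariates(covariates)
    cbind(age = cv$age, sex = cv$sex)
  }
  s1 <- colMeans(fit$posterior)
  s2 <- colMeans(fit$posterior_day2)
  if (K == 1L) {
    u <- stats::setNames(1, "class1")
    return(list(usual = u, s1 = s1, s2 = s2, mode = mode))
  }
  if (mode == "aggregate") {
    P <- aggregate_transition_matrix(fit, covariates)
    u <- stationary(P)
    names(u) <- paste0("class", seq_len(K))
    return(list(usual = u, s1 = s1, s2 = s2, mode = mode, matrix = P))
  }
  Pt <- subject_transitions(params, X)
  bad <- which(apply(Pt, 1L, min) <= 0)
  if (length(bad)) {
    stop("non-regular per-subject transition matrix for subject(s): ",
         paste(utils::head(rownames(X)[bad] %||% bad, 5L), collapse = ", "))
  }
  per <- t(apply(Pt, 1L, function(p) stationary_solve(matrix(p, K, K))))
  colnames(per) <- paste0("class", seq_len(K))
  u <- colMeans(per)
  list(usual = u, s1 = s1, s2 = s2, mode = mode, per_subject = per)
}
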