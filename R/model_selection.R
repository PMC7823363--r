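#' Akaike and Bayesian information criteria
#'
#' `AIC = -2 logLik + 2 p`; `BIC = -2 logLik + p log N`.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters.
#' @param N number of subjects.
#' @return list with `aic` and `bic`.
#' @export
information_criteria <- function(loglik, n_params, N) {
  stopifnot(N >= 1)
  list(aic = -2 * loglik + 2 * n_params,
       bic = -2 * loglik + n_params * log(N))
}

#' Relative entropy of a posterior classification
#'
#' One minus the average classification uncertainty, normalized by its
#' maximum `log K`: `1 - sum_i sum_k (-p_ik log p_ik) / (N log K)`.
#' Ranges from 0 (posteriors uniform: the classes tell nothing) to 1
#' (posteriors degenerate: perfect separation). For `K = 1` no
#' classification uncertainty is possible; the value is defined as 1,
#' with a warning.
#'
#' @param posterior N x K matrix with rows summing to 1.
#' @param K number of classes (defaults to `ncol(posterior)`).
#' @return scalar in `[0, 1]`.
#' @export
relative_entropy <- function(posterior, K = ncol(posterior)) {
  if (K == 1L) {
    warning("relative entropy is undefined for a single class; returning 1")
    return(1)
  }
  p <- posterior
  h <- ifelse(p > 0, -p * log(p), 0)
  1 - sum(h) / (nrow(p) * log(K))
}

#' Count the free parameters of a model specification
#'
#' Latent class model: `J K (C - 1)` item-response probabilities plus
#' `(K - 1)(1 + p)` membership-logit coefficients. Latent transition
#' model with measurement-invariant item responses: the same plus
#' `K (K - 1)` transition intercepts; without the shared-covariate
#' constraint, a further `(K - 1) p` destination slopes.
#'
#' @param type `"lca"` or `"lta"`.
#' @param K classes; @param J items; @param C categories per item.
#' @param n_covariates number of concomitant covariates (default 2).
#' @param constrained for `"lta"`, whether the covariate effects are
#'   shared between the day-1 membership and the transition logits.
#' @return integer count.
#' @export
count_params <- function(type = c("lca", "lta"), K, J, C = 3L,
                         n_covariates = 2L, constrained = TRUE) {
  type <- match.arg(type)
  base <- J * K * (C - 1L) + (K - 1L) * (1L + n_covariates)
  if (type == "lca") return(base)
  n <- base + K * (K - 1L)
  if (!constrained) n <- n + (K - 1L) * n_covariates
  n
}

#' Fit a grid of class numbers and tabulate fit indices
#'
#' Fits the requested model for each `K` with a shared multiple-start
#' protocol, and flags the BIC-minimizing row as selected. All criteria
#' (log-likelihood, AIC, BIC, relative entropy) are reported so the
#' automatic choice can be weighed qualitatively, as is usual when
#' choosing the number of dietary patterns.
#'
#' @param ordinal ordinal table (single day for `"lca"`, two days for
#'   `"lta"`).
#' @param covariates covariate table.
#' @param model `"lca"` or `"lta"`.
#' @param K_range integer vector of class numbers to try.
#' @param n_starts,seed,tol,max_iter start protocol shared across `K`.
#' @param ... further arguments passed to the fitting function (e.g.
#'   `constrain_covariates` for `"lta"`).
#' @return list with `table` (the selection data.frame), `fits` (one per
#'   `K`), and `selected` (the BIC-minimizing `K`).
#' @export
fit_grid <- function(ordinal, covariates, model = c("lca", "lta"),
                     K_range, n_starts = 20L, seed = 1L, tol = 1e-8,
                     max_iter = 1000L, ...) {
  model <- match.arg(model)
  stopifnot(length(K_range) >= 1L)
  set.seed(seed)
  k_seeds <- sample.int(.Machine$integer.max, length(K_range))
  fits <- vector("list", length(K_range))
  rows <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    fit <- if (model == "lca") {
      lca_em_fit(ordinal, covariates, K = K, n_starts = n_starts,
                 seed = k_seeds[i], tol = tol, max_iter = max_iter)
    } else {
      lta_em_fit(ordinal, covariates, K = K, n_starts = n_starts,
                 seed = k_seeds[i], tol = tol, max_iter = max_iter, ...)
    }
    fits[[i]] <- fit
    rows[[i]] <- data.frame(model = model, K = K, loglik = fit$loglik,
                            n_params = fit$n_params, aic = fit$aic,
                            bic = fit$bic, entropy = fit$entropy,
                            converged = fit$converged, seed = k_seeds[i])
  }
  table <- do.call(rbind, rows)
  table$selected <- table$bic == min(table$bic)
  if (any(!table$converged)) {
    warning("some class numbers did not converge: K = ",
            paste(table$K[!table$converged], collapse = ", "))
  }
  list(table = table, fits = fits, selected = table$K[which.min(table$bic)])
}
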