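#' Log-likelihood of a latent class model with concomitant covariates
#'
#' The model: each subject belongs to one of `K` latent dietary patterns;
#' class membership follows a multinomial logit on the covariates (class
#' `K` is the reference); given the class, the ordinal food-group
#' indicators are independent with class-conditional category
#' probabilities `rho[item, class, category]`.
#'
#' @param params list with `K`, `rho` (J x K x C array, rows over
#'   categories summing to 1) and `beta` ((K-1) x (1 + p) matrix of
#'   membership-logit coefficients, columns `(Intercept)`, `age`, `sex`,
#'   on the raw covariate scale).
#' @param ordinal single-day ordinal table (`subject_id`, `day`, `item`,
#'   `category`).
#' @param covariates covariate table (see [validate_covariates()]).
#' @param prob_floor lower bound applied to `rho` before taking logs, so
#'   that a zero estimated probability at an observed category yields a
#'   very small likelihood rather than `NaN`. Set to 0 for the exact
#'   (possibly `-Inf`) value.
#' @return scalar log-likelihood.
#' @export
lca_loglik <- function(params, ordinal, covariates, prob_floor = 0) {
  md <- build_model_data(ordinal, covariates)
  if (length(md$Y) != 1L) {
    stop("lca_loglik expects a single-day ordinal table; got ",
         length(md$Y), " days")
  }
  rho <- params$rho
  if (prob_floor > 0) rho <- pmax(rho, prob_floor)
  logem <- emission_loglik(log(rho), md$Y[[1L]])
  lp <- class_logprobs(params$beta, md$X, params$K)
  sum(row_logsumexp(lp + logem))
}

# log P(C = k | x) for all subjects; beta on the scale of X.
class_logprobs <- function(beta, X, K) {
  N <- nrow(X)
  if (K == 1L) return(matrix(0, N, 1L))
  D <- cbind(1, X)
  eta <- cbind(D %*% t(beta), 0)
  eta - row_logsumexp(eta)
}

#' Fit a latent class model by EM with multiple random starts
#'
#' E-step: posterior class probabilities proportional to the product of
#' the covariate-conditional prior and the item likelihood. M-step:
#' `rho` by posterior-weighted category proportions; membership-logit
#' coefficients by weighted multinomial-logistic maximization
#' (warm-started BFGS), making each iteration a generalized-EM step.
#' The best of `n_starts` random initializations is returned, with
#' classes relabeled in decreasing order of estimated size (class `K`,
#' the smallest, is the logit reference).
#'
#' Age is standardized internally for optimizer stability; reported
#' coefficients are on the years scale. During EM, `rho` is kept at
#' least `prob_floor` (exact constrained M-step), which prevents
#' log-of-zero without breaking monotonicity; the reported `rho` are the
#' un-floored posterior-weighted proportions.
#'
#' @inheritParams lca_loglik
#' @param K number of latent classes (>= 1).
#' @param n_starts number of random initializations.
#' @param seed integer seed making the whole fit reproducible.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations per start.
#' @param prob_floor minimum item-response probability during EM.
#' @return object of class `lca_fit`: `params`, `loglik`, `aic`, `bic`,
#'   `entropy`, `n_params`, `posterior`, `modal`, `converged`,
#'   `iterations`, `loglik_trace`, `starts` (per-start bookkeeping),
#'   `N`, `subjects`, `items`.
#' @export
lca_em_fit <- function(ordinal, covariates, K, n_starts = 20L, seed = 1L,
                       tol = 1e-8, max_iter = 1000L, prob_floor = 1e-6) {
  stopifnot(K >= 1L, n_starts >= 1L)
  md <- build_model_data(ordinal, covariates)
  if (length(md$Y) != 1L) stop("lca_em_fit expects a single-day ordinal table")
  std <- standardize_covariates(md$X)
  D <- cbind(1, std$Xs)
  Ymat <- md$Y[[1L]]
  set.seed(seed)
  start_seeds <- sample.int(.Machine$integer.max, n_starts)

  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    set.seed(start_seeds[s])
    rho <- init_random_rho(md$J, K, md$C)
    beta <- if (K > 1L) {
      matrix(stats::rnorm((K - 1L) * ncol(D), 0, 0.2), K - 1L, ncol(D))
    } else matrix(numeric(0), 0L, ncol(D))
    runs[[s]] <- lca_em_one(Ymat, std$Xs, D, rho, beta, K, md$C,
                            tol, max_iter, prob_floor)
    runs[[s]]$seed <- start_seeds[s]
  }
  lls <- vapply(runs, function(r) r$loglik, numeric(1))
  best <- runs[[which.max(lls)]]

  starts <- data.frame(start = seq_len(n_starts), seed = start_seeds,
                       loglik = lls,
                       converged = vapply(runs, `[[`, logical(1), "converged"),
                       iterations = vapply(runs, `[[`, integer(1), "iterations"))

  # canonical relabeling by decreasing class size
  sizes <- colMeans(best$posterior)
  perm <- order(sizes, decreasing = TRUE)
  rho <- best$rho_raw[, perm, , drop = FALSE]
  rho_fl <- best$rho[, perm, , drop = FALSE]
  posterior <- best$posterior[, perm, drop = FALSE]
  beta_std <- relabel_logit(best$beta, perm, K)
  dimnames(rho) <- dimnames(rho_fl) <-
    list(md$items, paste0("class", seq_len(K)), c("nil", "le_median", "gt_median"))
  colnames(posterior) <- paste0("class", seq_len(K))
  rownames(posterior) <- md$subjects

  beta <- beta_std
  if (K > 1L) {
    colnames(beta) <- c("(Intercept)", colnames(md$X))
    beta <- unstandardize_beta(beta, std$age_mean, std$age_sd)
    rownames(beta) <- paste0("class", seq_len(K - 1L))
  }

  modal <- classify_modal(posterior)
  n_params <- count_params("lca", K = K, J = md$J, C = md$C,
                           n_covariates = ncol(md$X))
  stopifnot(n_params ==
              md$J * K * (md$C - 1L) + (K - 1L) * (1L + ncol(md$X)))
  ic <- information_criteria(best$loglik, n_params, md$N)
  if (min(colSums(posterior)) < 1e-3) {
    warning("a latent class has near-zero posterior mass (degenerate fit)")
  }

  structure(list(
    params = list(K = K, rho = rho, beta = beta),
    rho_internal = rho_fl,
    loglik = best$loglik, aic = ic$aic, bic = ic$bic,
    entropy = if (K == 1L) 1 else relative_entropy(posterior),
    n_params = n_params,
    posterior = posterior, modal = modal,
    converged = best$converged, iterations = best$iterations,
    loglik_trace = best$trace, starts = starts,
    N = md$N, subjects = md$subjects, items = md$items,
    age_scaling = c(mean = std$age_mean, sd = std$age_sd),
    model = "lca"
  ), class = "lca_fit")
}

# Dirichlet(1,...,1) category rows per (item, class).
init_random_rho <- function(J, K, C) {
  x <- array(stats::rexp(J * K * C), dim = c(J, K, C))
  sw <- apply(x, c(1L, 2L), sum)
  for (cc in seq_len(C)) x[, , cc] <- x[, , cc] / sw
  x
}

# Re-express reference-K logit coefficients after permuting classes:
# the new row k is the old linear predictor of perm[k] minus that of
# perm[K] (predictor differences are linear in the coefficients).
relabel_logit <- function(beta, perm, K) {
  if (K == 1L) return(beta)
  full <- rbind(beta, 0)
  out <- full[perm[-K], , drop = FALSE] -
    matrix(full[perm[K], ], K - 1L, ncol(full), byrow = TRUE)
  out
}

lca_em_one <- function(Ymat, Xs, D, rho, beta, K, C, tol, max_iter,
                       prob_floor) {
  J <- nrow(rho)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  posterior <- NULL
  rho_raw <- rho
  repeat {
    it <- it + 1L
    lp <- if (K > 1L) {
      eta <- cbind(D %*% t(beta), 0)
      eta - row_logsumexp(eta)
    } else matrix(0, nrow(Ymat), 1L)
    logw <- lp + emission_loglik(log(rho), Ymat)
    lse <- row_logsumexp(logw)
    ll <- sum(lse)
    trace <- c(trace, ll)
    posterior <- exp(logw - lse)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_old <- ll
    # M-step: item-response probabilities
    rho_raw <- array(0, dim = dim(rho))
    for (cc in seq_len(C)) {
      Ind <- (Ymat == cc - 1L)
      rho_raw[, , cc] <- crossprod(Ind, posterior)  # J x K counts
    }
    for (j in seq_len(J)) for (k in seq_len(K)) {
      cnt <- rho_raw[j, k, ]
      rho[j, k, ] <- floor_simplex(cnt, prob_floor)
      rho_raw[j, k, ] <- if (sum(cnt) > 0) cnt / sum(cnt) else rep(1 / C, C)
    }
    # M-step: membership logit
    if (K > 1L) beta <- wmnl_fit(D, posterior, beta)
  }
  list(rho = rho, rho_raw = rho_raw, beta = beta, loglik = ll,
       posterior = posterior, converged = converged, iterations = it,
       trace = trace)
}

#' Posterior class-membership probabilities
#'
#' @inheritParams lca_loglik
#' @return N x K matrix of normalized posterior probabilities.
#' @export
lca_posterior <- function(params, ordinal, covariates, prob_floor = 1e-12) {
  md <- build_model_data(ordinal, covariates)
  rho <- pmax(params$rho, prob_floor)
  logem <- emission_loglik(log(rho), md$Y[[1L]])
  lp <- class_logprobs(params$beta, md$X, params$K)
  logw <- lp + logem
  post <- exp(logw - row_logsumexp(logw))
  rownames(post) <- md$subjects
  colnames(post) <- paste0("class", seq_len(params$K))
  post
}

#' Modal class assignment
#'
#' Each subject is assigned to the class with the highest posterior
#' probability; exact ties go to the lowest class index and the number
#' of ties is recorded in the `"ties"` attribute (and messaged).
#'
#' @param posterior N x K matrix with rows summing to 1.
#' @return integer vector of class labels with attribute `ties`.
#' @export
classify_modal <- function(posterior) {
  labels <- apply(posterior, 1L, which.max)  # which.max takes first max
  n_ties <- sum(apply(posterior, 1L, function(r) sum(r == max(r)) > 1L))
  if (n_ties > 0L) {
    message(n_ties, " subject(s) had tied posteriors; assigned to the ",
            "lowest class index")
  }
  structure(as.integer(labels), ties = n_ties)
}

#' Class-conditional food-group consumption profile
#'
#' For each class and food group, the (posterior-weighted) percentage of
#' subjects in each consumption category (nil / at-or-below median /
#' above median); rows sum to 100. This is the table used to name and
#' interpret the dietary patterns.
#'
#' @param ordinal single-day ordinal table.
#' @param posterior N x K posterior matrix (rows aligned with sorted
#'   subject ids); if `labels` is given instead, hard assignment is used.
#' @param labels optional integer class labels.
#' @return data.frame `class`, `item`, `category`, `percent`.
#' @export
class_profile_table <- function(ordinal, posterior = NULL, labels = NULL) {
  subjects <- sort(unique(ordinal$subject_id))
  items <- sort(unique(ordinal$item))
  if (is.null(posterior)) {
    if (is.null(labels)) stop("supply posterior or labels")
    K <- max(labels)
    posterior <- matrix(0, length(subjects), K)
    posterior[cbind(seq_along(subjects), labels)] <- 1
  }
  K <- ncol(posterior)
  cats <- c("nil", "le_median", "gt_median")
  out <- expand.grid(class = seq_len(K), item = items,
                     category = cats, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$percent <- NA_real_
  si <- match(ordinal$subject_id, subjects)
  for (k in seq_len(K)) {
    w <- posterior[si, k]
    for (it in items) {
      sel <- ordinal$item == it
      tot <- sum(w[sel])
      for (cc in 0:2) {
        pct <- if (tot > 0) 100 * sum(w[sel & ordinal$category == cc]) / tot
               else NA_real_
        out$percent[out$class == k & out$item == it &
                      out$category == cats[cc + 1L]] <- pct
      }
    }
  }
  out
}

#' @export
print.lca_fit <- function(x, ...) {
  cat("Latent class model (", x$params$K, " classes, N = ", x$N,
      ", J = ", length(x$items), " items)\n", sep = "")
  cat(sprintf("  logLik %.3f  AIC %.3f  BIC %.3f  entropy %.3f\n",
              x$loglik, x$aic, x$bic, x$entropy))
  cat("  class sizes:",
      paste(sprintf("%.1f%%", 100 * colMeans(x$posterior)), collapse = " "),
      "\n")
  cat("  converged:", x$converged, "in", x$iterations, "iterations\n")
  invisible(x)
}
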