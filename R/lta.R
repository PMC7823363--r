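#' Log-likelihood of the two-day latent transition model
#'
#' Day-1 class membership follows a multinomial logit on the covariates
#' (`beta1`); the day-2 class follows a multinomial logit on the day-1
#' class (transition intercepts `trans_a`) and the covariates (`gamma`);
#' item responses on both days share one set of class-conditional
#' category probabilities `rho` (measurement invariance). The
#' likelihood sums over all `K^2` latent (day-1, day-2) paths:
#' `sum_i log sum_k sum_l P(C1=k|x) P(C2=l|C1=k,x) prod_j rho[j,k,y1] rho[j,l,y2]`.
#'
#' @param params list with `K`, `rho` (J x K x C), `beta1`
#'   ((K-1) x (1+p), reference class K), `trans_a` (K x (K-1) transition
#'   intercepts, reference destination K), `gamma` ((K-1) x p destination
#'   covariate slopes; equals the covariate block of `beta1` when the
#'   concomitant effects are constrained equal across days). All on the
#'   raw covariate scale.
#' @param ordinal two-day ordinal table.
#' @param covariates covariate table.
#' @param prob_floor lower bound on `rho` before logs (see [lca_loglik()]).
#' @return scalar log-likelihood.
#' @export
lta_loglik <- function(params, ordinal, covariates, prob_floor = 0) {
  md <- build_model_data(ordinal, covariates)
  if (length(md$Y) != 2L) {
    stop("lta_loglik expects a two-day ordinal table; got ",
         length(md$Y), " day(s)")
  }
  lta_loglik_mat(params, md$Y[[1L]], md$Y[[2L]], md$X, prob_floor)
}

# Matrix-level log-likelihood (internal hot path).
lta_loglik_mat <- function(params, Y1, Y2, X, prob_floor = 0) {
  K <- params$K
  rho <- params$rho
  if (prob_floor > 0) rho <- pmax(rho, prob_floor)
  logrho <- log(rho)
  L1 <- emission_loglik(logrho, Y1)
  L2 <- emission_loglik(logrho, Y2)
  lp1 <- class_logprobs(params$beta1, X, K)
  lt <- build_logtrans(params$trans_a, params$gamma, X)
  M <- matrix(-Inf, nrow(X), K * K)
  for (k in seq_len(K)) for (l in seq_len(K)) {
    M[, (k - 1L) * K + l] <- lp1[, k] + L1[, k] + lt[, k, l] + L2[, l]
  }
  sum(row_logsumexp(M))
}

#' Fit the latent transition model by EM with multiple random starts
#'
#' The E-step computes joint posteriors `q_i(k, l)` over day-1/day-2
#' class pairs by direct enumeration of the `K^2` paths (with only two
#' occasions no forward-backward recursion is needed). The M-step
#' updates `rho` from posterior-weighted category counts pooled over
#' both days (measurement invariance), and the logit blocks by
#' warm-started BFGS maximization of the expected complete-data
#' log-likelihood. With `constrain_covariates = TRUE` (default) the
#' covariate slopes of the day-1 membership logit and of the day-2
#' transition logit are a single shared block, maximized jointly, so
#' the concomitant effects are the same on both days.
#'
#' Classes are relabeled by decreasing day-1 size; age is standardized
#' internally and coefficients reported on the years scale.
#'
#' @inheritParams lta_loglik
#' @param K number of latent classes.
#' @param n_starts,seed,tol,max_iter,prob_floor as in [lca_em_fit()].
#' @param constrain_covariates share covariate effects across days.
#' @return object of class `lta_fit`; in addition to the [lca_em_fit()]
#'   fields it carries `posterior` (day-1), `posterior_day2`, the joint
#'   posterior array `joint_posterior`, and the model data needed by
#'   [aggregate_transition_matrix()], [membership_odds_ratios()] and
#'   [usual_prevalence()].
#' @export
lta_em_fit <- function(ordinal, covariates, K, n_starts = 20L, seed = 1L,
                       tol = 1e-8, max_iter = 1000L, prob_floor = 1e-6,
                       constrain_covariates = TRUE) {
  stopifnot(K >= 1L, n_starts >= 1L)
  md <- build_model_data(ordinal, covariates)
  if (length(md$Y) != 2L) stop("lta_em_fit expects a two-day ordinal table")
  std <- standardize_covariates(md$X)
  D <- cbind(1, std$Xs)
  p <- ncol(md$X)
  set.seed(seed)
  start_seeds <- sample.int(.Machine$integer.max, n_starts)

  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    set.seed(start_seeds[s])
    init <- list(
      rho = init_random_rho(md$J, K, md$C),
      beta1 = matrix(stats::rnorm((K - 1L) * (1L + p), 0, 0.2), K - 1L, 1L + p),
      a = matrix(stats::rnorm(K * (K - 1L), 0, 0.2), K, K - 1L),
      gamma = matrix(stats::rnorm((K - 1L) * p, 0, 0.2), K - 1L, p)
    )
    if (constrain_covariates && K > 1L) {
      init$gamma <- init$beta1[, -1L, drop = FALSE]
    }
    runs[[s]] <- lta_em_one(md$Y[[1L]], md$Y[[2L]], std$Xs, D, init, K,
                            md$C, tol, max_iter, prob_floor,
                            constrain_covariates)
    runs[[s]]$seed <- start_seeds[s]
  }
  lls <- vapply(runs, function(r) r$loglik, numeric(1))
  best <- runs[[which.max(lls)]]
  starts <- data.frame(start = seq_len(n_starts), seed = start_seeds,
                       loglik = lls,
                       converged = vapply(runs, `[[`, logical(1), "converged"),
                       iterations = vapply(runs, `[[`, integer(1), "iterations"))

  # relabel by decreasing day-1 class size
  p1 <- apply(best$q, c(1L, 2L), sum)
  p2 <- apply(best$q, c(1L, 3L), sum)
  perm <- order(colMeans(p1), decreasing = TRUE)
  rho <- best$rho_raw[, perm, , drop = FALSE]
  rho_fl <- best$rho[, perm, , drop = FALSE]
  q <- best$q[, perm, perm, drop = FALSE]
  p1 <- p1[, perm, drop = FALSE]
  p2 <- p2[, perm, drop = FALSE]
  beta1 <- relabel_logit(best$beta1, perm, K)
  afull <- cbind(best$a, 0)
  gfull <- rbind(best$gamma, 0)
  trans_a <- matrix(0, K, max(K - 1L, 0L))
  gamma <- relabel_logit(best$gamma, perm, K)  # same difference rule, no intercept
  if (K > 1L) {
    for (k in seq_len(K)) {
      trans_a[k, ] <- afull[perm[k], perm[-K]] - afull[perm[k], perm[K]]
    }
  }

  # back to the years scale: slopes divide by sd(age), intercept-like
  # terms absorb the mean shift
  cn <- c("(Intercept)", colnames(md$X))
  if (K > 1L) {
    dimnames(beta1) <- list(paste0("class", seq_len(K - 1L)), cn)
    beta1 <- unstandardize_beta(beta1, std$age_mean, std$age_sd)
    colnames(gamma) <- colnames(md$X)
    age_col <- match("age", colnames(gamma))
    trans_a <- trans_a -
      matrix(gamma[, age_col] * std$age_mean / std$age_sd,
             K, K - 1L, byrow = TRUE)
    gamma[, age_col] <- gamma[, age_col] / std$age_sd
    rownames(gamma) <- paste0("class", seq_len(K - 1L))
    dimnames(trans_a) <- list(paste0("from", seq_len(K)),
                              paste0("to", seq_len(K - 1L)))
  }
  dimnames(rho) <- dimnames(rho_fl) <-
    list(md$items, paste0("class", seq_len(K)),
         c("nil", "le_median", "gt_median"))
  dimnames(p1) <- dimnames(p2) <-
    list(md$subjects, paste0("class", seq_len(K)))

  n_params <- count_params("lta", K = K, J = md$J, C = md$C,
                           n_covariates = p,
                           constrained = constrain_covariates)
  ic <- information_criteria(best$loglik, n_params, md$N)
  joint_flat <- matrix(q, md$N, K * K)
  entropy <- if (K == 1L) 1 else 1 - sum(ifelse(joint_flat > 0,
    -joint_flat * log(joint_flat), 0)) / (md$N * log(K * K))

  params <- list(K = K, rho = rho, beta1 = beta1, trans_a = trans_a,
                 gamma = gamma, constrained = constrain_covariates)
  structure(list(
    params = params, rho_internal = rho_fl,
    loglik = best$loglik, aic = ic$aic, bic = ic$bic, entropy = entropy,
    n_params = n_params,
    posterior = p1, posterior_day2 = p2, joint_posterior = q,
    modal = classify_modal(p1),
    converged = best$converged, iterations = best$iterations,
    loglik_trace = best$trace, starts = starts,
    N = md$N, subjects = md$subjects, items = md$items,
    X = md$X, Y1 = md$Y[[1L]], Y2 = md$Y[[2L]],
    age_scaling = c(mean = std$age_mean, sd = std$age_sd),
    model = "lta"
  ), class = "lta_fit")
}

lta_em_one <- function(Y1, Y2, Xs, D, init, K, C, tol, max_iter,
                       prob_floor, constrained) {
  J <- ncol(Y1)
  N <- nrow(Y1)
  rho <- init$rho
  rho_raw <- rho
  beta1 <- init$beta1
  a <- init$a
  gamma <- init$gamma
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  q <- NULL
  # constant pieces hoisted out of the EM loop
  I1 <- lapply(seq_len(C), function(cc) Y1 == cc - 1L)
  I2 <- lapply(seq_len(C), function(cc) Y2 == cc - 1L)
  S1sel <- matrix(0, K * K, K)  # (k,l) column-index -> k margin
  S2sel <- matrix(0, K * K, K)  # (k,l) column-index -> l margin
  for (k in seq_len(K)) for (l in seq_len(K)) {
    S1sel[(k - 1L) * K + l, k] <- 1
    S2sel[(k - 1L) * K + l, l] <- 1
  }
  repeat {
    it <- it + 1L
    logrho <- log(rho)
    L1 <- emission_loglik(logrho, Y1)
    L2 <- emission_loglik(logrho, Y2)
    lp1 <- if (K > 1L) {
      eta <- cbind(D %*% t(beta1), 0)
      eta - row_logsumexp(eta)
    } else matrix(0, N, 1L)
    lt <- build_logtrans(a, gamma, Xs)
    M <- matrix(-Inf, N, K * K)
    for (k in seq_len(K)) for (l in seq_len(K)) {
      M[, (k - 1L) * K + l] <- lp1[, k] + L1[, k] + lt[, k, l] + L2[, l]
    }
    lse <- row_logsumexp(M)
    ll <- sum(lse)
    trace <- c(trace, ll)
    W <- exp(M - lse)
    q <- array(0, dim = c(N, K, K))
    for (k in seq_len(K)) for (l in seq_len(K)) {
      q[, k, l] <- W[, (k - 1L) * K + l]
    }
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_old <- ll
    p1 <- W %*% S1sel
    p2 <- W %*% S2sel
    # measurement-invariant rho: category counts pooled over both days
    rho_raw <- array(0, dim = c(J, K, C))
    for (cc in seq_len(C)) {
      rho_raw[, , cc] <- crossprod(I1[[cc]], p1) + crossprod(I2[[cc]], p2)
    }
    for (j in seq_len(J)) for (k in seq_len(K)) {
      cnt <- rho_raw[j, k, ]
      rho[j, k, ] <- floor_simplex(cnt, prob_floor)
      rho_raw[j, k, ] <- if (sum(cnt) > 0) cnt / sum(cnt) else rep(1 / C, C)
    }
    if (K > 1L) {
      if (constrained) {
        upd <- constrained_mstep(Xs, q, p1, beta1[, 1L],
                                 beta1[, -1L, drop = FALSE], a)
        beta1 <- cbind(upd$b0, upd$g)
        gamma <- upd$g
        a <- upd$a
      } else {
        beta1 <- wmnl_fit(D, p1, beta1)
        upd <- trans_mstep(Xs, q, p1, a, gamma)
        a <- upd$a
        gamma <- upd$gamma
      }
    }
  }
  list(rho = rho, rho_raw = rho_raw, beta1 = beta1, a = a, gamma = gamma,
       loglik = ll, q = q, converged = converged, iterations = it,
       trace = trace)
}

#' Covariate-conditional transition matrix
#'
#' The K x K row-stochastic matrix of day-to-day transition
#' probabilities at a given covariate vector: row `k` is the softmax
#' over destinations of `trans_a[k, l] + gamma[l, ] . x`, with
#' destination `K` as the reference.
#'
#' @param params fitted `lta_fit` parameters (or the fit itself).
#' @param x named covariate vector (`age` in years, `sex` 0/1).
#' @return K x K matrix with rows summing to 1.
#' @export
transition_matrix <- function(params, x) {
  if (inherits(params, "lta_fit")) params <- params$params
  K <- params$K
  X <- matrix(x, 1L, length(x))
  colnames(X) <- names(x)
  lt <- build_logtrans(params$trans_a, params$gamma, X)
  P <- matrix(exp(lt[1L, , ]), K, K)
  dimnames(P) <- list(paste0("from", seq_len(K)), paste0("to", seq_len(K)))
  P
}

# Per-subject transition matrices as an N x K x K array.
subject_transitions <- function(params, X) {
  exp(build_logtrans(params$trans_a, params$gamma, X))
}

#' Cohort-level (aggregate) transition matrix
#'
#' Row `k` is the average of the subjects' covariate-conditional
#' transition rows, weighted by each subject's day-1 posterior
#' membership in class `k` -- the kind of whole-cohort transition
#' summary usually reported (e.g. the percentage following the same
#' pattern on both days).
#'
#' @param fit `lta_fit` object.
#' @param covariates optional covariate table; defaults to the fitting
#'   cohort stored in the fit.
#' @return K x K row-stochastic matrix.
#' @export
aggregate_transition_matrix <- function(fit, covariates = NULL) {
  params <- fit$params
  K <- params$K
  if (is.null(covariates)) {
    X <- fit$X
    w <- fit$posterior
  } else {
    covariates <- validate_covariates(covariates)
    X <- cbind(age = covariates$age, sex = covariates$sex)
    # without refitting, weight new subjects by the model-implied
    # day-1 membership probabilities
    w <- exp(class_logprobs(params$beta1, X, K))
  }
  if (nrow(X) == 0L) stop("empty cohort")
  Pt <- subject_transitions(params, X)
  P <- matrix(0, K, K)
  for (k in seq_len(K)) {
    wk <- w[, k]
    P[k, ] <- colSums(wk * matrix(Pt[, k, ], nrow(X), K)) / sum(wk)
  }
  dimnames(P) <- list(paste0("from", seq_len(K)), paste0("to", seq_len(K)))
  P
}

#' Transition probabilities along a covariate grid
#'
#' Evaluates every transition-matrix entry over a grid of ages for each
#' sex, for plotting how day-to-day pattern stability varies with the
#' concomitant covariates.
#'
#' @param params `lta_fit` or its `params`.
#' @param age_grid numeric vector of ages (years).
#' @param sexes sex codes to evaluate (default both 0 and 1).
#' @return long data.frame `age`, `sex`, `from`, `to`, `probability`.
#' @export
transition_curves <- function(params, age_grid = 18:84, sexes = c(0, 1)) {
  if (inherits(params, "lta_fit")) params <- params$params
  K <- params$K
  out <- list()
  for (sx in sexes) {
    X <- cbind(age = age_grid, sex = sx)
    Pt <- subject_transitions(params, X)
    for (k in seq_len(K)) for (l in seq_len(K)) {
      out[[length(out) + 1L]] <- data.frame(
        age = age_grid, sex = sx, from = k, to = l,
        probability = Pt[, k, l])
    }
  }
  do.call(rbind, out)
}

#' @export
print.lta_fit <- function(x, ...) {
  cat("Latent transition model (", x$params$K, " classes, N = ", x$N,
      ", J = ", length(x$items), " items, 2 days)\n", sep = "")
  cat(sprintf("  logLik %.3f  AIC %.3f  BIC %.3f  entropy %.3f\n",
              x$loglik, x$aic, x$bic, x$entropy))
  cat("  day-1 class sizes:",
      paste(sprintf("%.1f%%", 100 * colMeans(x$posterior)), collapse = " "),
      "\n")
  cat("  covariate effects constrained equal across days:",
      x$params$constrained, "\n")
  P <- aggregate_transition_matrix(x)
  cat("  aggregate transition diagonal:",
      paste(sprintf("%.1f%%", 100 * diag(P)), collapse = " "), "\n")
  invisible(x)
}
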