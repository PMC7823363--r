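# Brute-force likelihood oracles: plain loops over subjects and latent
# paths, sharing no code with the vectorized implementation.

softmax1 <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}

# P(C1 = k | x) for one subject from a reference-K logit matrix.
oracle_class_probs <- function(beta, x, K) {
  if (K == 1L) return(1)
  eta <- numeric(K)
  for (k in seq_len(K - 1L)) eta[k] <- sum(beta[k, ] * c(1, x))
  softmax1(eta)
}

oracle_trans_row <- function(trans_a, gamma, x, k, K) {
  if (K == 1L) return(1)
  eta <- numeric(K)
  for (l in seq_len(K - 1L)) eta[l] <- trans_a[k, l] + sum(gamma[l, ] * x)
  softmax1(eta)
}

# LCA log-likelihood by direct enumeration of classes per subject.
# Y: N x J categories 0..2, X: N x 2 covariates.
oracle_lca_loglik <- function(params, Y, X) {
  K <- params$K
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    pri <- oracle_class_probs(params$beta, X[i, ], K)
    tot <- 0
    for (k in seq_len(K)) {
      lik <- pri[k]
      for (j in seq_len(ncol(Y))) {
        lik <- lik * params$rho[j, k, Y[i, j] + 1L]
      }
      tot <- tot + lik
    }
    ll <- ll + log(tot)
  }
  ll
}

# LTA log-likelihood by exhaustive enumeration of all (k, l) paths.
oracle_lta_loglik <- function(params, Y1, Y2, X) {
  K <- params$K
  ll <- 0
  for (i in seq_len(nrow(Y1))) {
    pri <- oracle_class_probs(params$beta1, X[i, ], K)
    tot <- 0
    for (k in seq_len(K)) {
      tr <- oracle_trans_row(params$trans_a, params$gamma, X[i, ], k, K)
      for (l in seq_len(K)) {
        lik <- pri[k] * tr[l]
        for (j in seq_len(ncol(Y1))) {
          lik <- lik * params$rho[j, k, Y1[i, j] + 1L] *
            params$rho[j, l, Y2[i, j] + 1L]
        }
        tot <- tot + lik
      }
    }
    ll <- ll + log(tot)
  }
  ll
}

# Turn category matrices into the long ordinal data.frame the package
# functions consume.
matrices_to_ordinal <- function(Y1, Y2 = NULL) {
  ids <- sprintf("S%03d", seq_len(nrow(Y1)))
  items <- sprintf("it%02d", seq_len(ncol(Y1)))
  out <- data.frame(subject_id = rep(ids, ncol(Y1)), day = 1L,
                    item = rep(items, each = nrow(Y1)),
                    category = as.vector(Y1))
  if (!is.null(Y2)) {
    out <- rbind(out, data.frame(subject_id = rep(ids, ncol(Y2)), day = 2L,
                                 item = rep(items, each = nrow(Y2)),
                                 category = as.vector(Y2)))
  }
  out
}

covariates_for <- function(X) {
  data.frame(subject_id = sprintf("S%03d", seq_len(nrow(X))),
             age = X[, 1L], sex = X[, 2L])
}

# Random hand-set parameters for tiny instances.
random_params <- function(K, J, seed, lta = FALSE) {
  set.seed(seed)
  rho <- array(stats::rexp(J * K * 3), dim = c(J, K, 3))
  sw <- apply(rho, c(1, 2), sum)
  for (cc in 1:3) rho[, , cc] <- rho[, , cc] / sw
  beta <- matrix(stats::rnorm((K - 1) * 3, 0, 0.5), K - 1, 3)
  colnames(beta) <- c("(Intercept)", "age", "sex")
  if (!lta) return(list(K = K, rho = rho, beta = beta))
  list(K = K, rho = rho, beta1 = beta,
       trans_a = matrix(stats::rnorm(K * (K - 1), 0, 0.5), K, K - 1),
       gamma = matrix(stats::rnorm((K - 1) * 2, 0, 0.3), K - 1, 2),
       constrained = FALSE)
}

# Tiny covariate matrix with ages in-range.
random_X <- function(N, seed) {
  set.seed(seed)
  cbind(age = stats::runif(N, 20, 80), sex = stats::rbinom(N, 1, 0.5))
}

# Random regular transition matrix (strictly positive rows).
random_regular_P <- function(K, seed) {
  set.seed(seed)
  P <- matrix(stats::rexp(K * K) + 0.05, K, K)
  P / rowSums(P)
}

# Small two-day intake fixture with known structure.
toy_intake <- function() {
  ids <- sprintf("P%02d", 1:4)
  expand.grid(subject_id = ids, day = 1:2,
              food_group = c("fruit", "fish"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    transform(amount = c(10, 20, 30, 40, 14, 16, 34, 36,
                         5, 0, 10, 40, 5, 0, 20, 40))
}
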