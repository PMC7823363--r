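# Internal M-step machinery for the multinomial-logistic (concomitant
# covariate) parts of the models.  Every maximization is warm-started at
# the current parameter value and the update is only accepted when the
# expected complete-data log-likelihood improves, so each EM iteration
# is a generalized-EM step and the observed log-likelihood cannot
# decrease.

# Weighted multinomial logit.  D: N x m design (first column 1), W: N x K
# nonnegative weights (class K is the reference).  Maximizes
# sum_ik W[i,k] log softmax_k(D_i B')  over B ((K-1) x m).
wmnl_fit <- function(D, W, B0, maxit = 50L, reltol = 1e-9) {
  K <- ncol(W)
  if (K == 1L) return(matrix(numeric(0), 0L, ncol(D)))
  m <- ncol(D)
  r <- rowSums(W)
  obj <- function(theta) {
    B <- matrix(theta, K - 1L, m)
    eta <- cbind(D %*% t(B), 0)
    lse <- row_logsumexp(eta)
    -sum(W * (eta - lse))
  }
  grad <- function(theta) {
    B <- matrix(theta, K - 1L, m)
    eta <- cbind(D %*% t(B), 0)
    pi <- row_softmax(eta)
    R <- W[, -K, drop = FALSE] - r * pi[, -K, drop = FALSE]
    -as.vector(t(R) %*% D)
  }
  th0 <- as.vector(B0)
  fit <- stats::optim(th0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  if (fit$value <= obj(th0)) {
    matrix(fit$par, K - 1L, m, dimnames = dimnames(B0))
  } else {
    B0
  }
}

# Transition log-probability array: T[i, k, l] = log P(C2 = l | C1 = k, x_i)
# with a: K x (K-1) intercepts (destination K is the reference) and
# gamma: (K-1) x p destination covariate slopes.
build_logtrans <- function(a, gamma, X) {
  K <- nrow(a)
  N <- nrow(X)
  out <- array(0, dim = c(N, K, K))
  G <- if (K > 1L) X %*% t(gamma) else matrix(0, N, 0)
  for (k in seq_len(K)) {
    eta <- cbind(sweep(G, 2L, a[k, , drop = TRUE], "+"),
                 rep(0, N))
    out[, k, ] <- eta - row_logsumexp(eta)
  }
  out
}

# M-step for the unconstrained transition block: maximize
# sum_ikl q[i,k,l] log P(C2 = l | C1 = k, x_i)  over (a, gamma).
trans_mstep <- function(X, q, p1, a0, gamma0, maxit = 25L, reltol = 1e-9) {
  K <- nrow(a0)
  p <- ncol(X)
  pack <- function(a, gamma) c(as.vector(a), as.vector(gamma))
  unpack <- function(th) {
    list(a = matrix(th[seq_len(K * (K - 1L))], K, K - 1L),
         gamma = matrix(th[-seq_len(K * (K - 1L))], K - 1L, p))
  }
  obj <- function(th) {
    pr <- unpack(th)
    lt <- build_logtrans(pr$a, pr$gamma, X)
    -sum(q * lt)
  }
  grad <- function(th) {
    pr <- unpack(th)
    lt <- build_logtrans(pr$a, pr$gamma, X)
    Pt <- exp(lt)
    ga <- matrix(0, K, K - 1L)
    gg <- matrix(0, K - 1L, p)
    for (k in seq_len(K)) {
      R <- matrix(q[, k, -K], nrow = nrow(X))
      E <- p1[, k] * matrix(Pt[, k, -K], nrow = nrow(X))
      ga[k, ] <- colSums(R - E)
      gg <- gg + t(R - E) %*% X
    }
    -c(as.vector(ga), as.vector(gg))
  }
  th0 <- pack(a0, gamma0)
  fit <- stats::optim(th0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  if (fit$value <= obj(th0)) unpack(fit$par) else list(a = a0, gamma = gamma0)
}

# M-step for the constrained model: the covariate slopes g are shared
# between the day-1 membership logit and the transition logit (the
# concomitant effects are the same on both days).  Maximizes jointly
#   sum_ik p1[i,k] log P(C1 = k | x_i; b0, g)
# + sum_ikl q[i,k,l] log P(C2 = l | C1 = k, x_i; a, g).
constrained_mstep <- function(X, q, p1, b00, g0, a0, maxit = 40L,
                              reltol = 1e-9) {
  K <- nrow(a0)
  p <- ncol(X)
  n_b <- K - 1L
  n_g <- (K - 1L) * p
  pack <- function(b0, g, a) c(b0, as.vector(g), as.vector(a))
  unpack <- function(th) {
    list(b0 = th[seq_len(n_b)],
         g = matrix(th[n_b + seq_len(n_g)], K - 1L, p),
         a = matrix(th[n_b + n_g + seq_len(K * (K - 1L))], K, K - 1L))
  }
  eta1_of <- function(b0, g) {
    cbind(sweep(X %*% t(g), 2L, b0, "+"), rep(0, nrow(X)))
  }
  obj <- function(th) {
    pr <- unpack(th)
    eta1 <- eta1_of(pr$b0, pr$g)
    lp1 <- eta1 - row_logsumexp(eta1)
    lt <- build_logtrans(pr$a, pr$g, X)
    -(sum(p1 * lp1) + sum(q * lt))
  }
  grad <- function(th) {
    pr <- unpack(th)
    eta1 <- eta1_of(pr$b0, pr$g)
    pi1 <- row_softmax(eta1)
    lt <- build_logtrans(pr$a, pr$g, X)
    Pt <- exp(lt)
    R1 <- p1[, -K, drop = FALSE] - pi1[, -K, drop = FALSE]
    gb0 <- colSums(R1)
    gg <- t(R1) %*% X
    ga <- matrix(0, K, K - 1L)
    for (k in seq_len(K)) {
      R <- matrix(q[, k, -K], nrow = nrow(X))
      E <- p1[, k] * matrix(Pt[, k, -K], nrow = nrow(X))
      ga[k, ] <- colSums(R - E)
      gg <- gg + t(R - E) %*% X
    }
    -c(gb0, as.vector(gg), as.vector(ga))
  }
  th0 <- pack(b00, g0, a0)
  fit <- stats::optim(th0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  if (fit$value <= obj(th0)) unpack(fit$par) else
    list(b0 = b00, g = g0, a = a0)
}
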