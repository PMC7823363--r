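# Internal numerical helpers shared across the estimation code.

# Row maxima without apply() overhead (hot path).
row_max <- function(M) {
  mx <- M[, 1L]
  nc <- ncol(M)
  if (nc > 1L) for (j in 2:nc) mx <- pmax(mx, M[, j])
  mx
}

# Row-wise log-sum-exp of a matrix; rows of all -Inf map to -Inf.
row_logsumexp <- function(M) {
  mx <- row_max(M)
  bad <- !is.finite(mx)
  mx[bad] <- 0
  out <- mx + log(rowSums(exp(M - mx)))
  out[bad] <- -Inf
  out
}

# Row-wise softmax of a matrix of linear predictors.
row_softmax <- function(M) {
  E <- exp(M - row_max(M))
  E / rowSums(E)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Exact maximizer of sum(counts * log(p)) over the simplex subject to
# p >= floor: water-filling on the floored coordinates.  Used by the
# M-step so that the probability floor never breaks EM monotonicity.
floor_simplex <- function(counts, floor = 0) {
  C <- length(counts)
  if (sum(counts) <= 0) return(rep(1 / C, C))
  p <- counts / sum(counts)
  if (floor <= 0 || all(p >= floor)) return(p)
  fixed <- rep(FALSE, C)
  repeat {
    free_mass <- 1 - floor * sum(fixed)
    p <- ifelse(fixed, floor, 0)
    cf <- counts[!fixed]
    if (sum(cf) <= 0) {
      p[!fixed] <- free_mass / sum(!fixed)
    } else {
      p[!fixed] <- free_mass * cf / sum(cf)
    }
    low <- !fixed & (p < floor)
    if (!any(low)) return(p)
    fixed <- fixed | low
    if (all(fixed)) return(rep(1 / C, C))
  }
}

# All permutations of 1:n (n small; class counts never exceed 7).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- cbind(i, sub + (sub >= i))
  }
  do.call(rbind, out)
}

# Optimal class-label assignment between two item-response arrays
# rho[j, k, c]: the permutation of columns of `cand` minimizing total
# absolute difference to `ref`.  Exhaustive over permutations, which is
# the exact solution of the assignment problem at these sizes.
match_classes <- function(ref, cand) {
  K <- dim(ref)[2]
  perms <- all_permutations(K)
  best <- NULL
  best_cost <- Inf
  for (r in seq_len(nrow(perms))) {
    pm <- perms[r, ]
    cost <- sum(abs(ref - cand[, pm, , drop = FALSE]))
    if (cost < best_cost) {
      best_cost <- cost
      best <- pm
    }
  }
  best
}

# Central-difference Hessian of scalar function f at x.
num_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  hh <- h * (1 + abs(x))
  H <- matrix(NA_real_, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    ei <- rep(0, n); ei[i] <- hh[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hh[i]^2
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        ej <- rep(0, n); ej[j] <- hh[j]
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * hh[i] * hh[j])
      }
    }
  }
  H
}

`%||%` <- function(a, b) if (is.null(a)) b else a
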