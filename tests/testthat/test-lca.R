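test_that("latent class log-likelihood matches direct enumeration and collapses correctly", {
  # hand-set params, brute-force oracle over classes
  for (seed in 1:5) {
    K <- sample(2:3, 1)
    J <- 2L
    params <- random_params(K, J, seed)
    X <- random_X(5L, seed + 100)
    set.seed(seed + 200)
    Y <- matrix(sample(0:2, 5 * J, replace = TRUE), 5L, J)
    ll <- lca_loglik(params, matrices_to_ordinal(Y), covariates_for(X))
    expect_equal(ll, oracle_lca_loglik(params, Y, X), tolerance = 1e-12)
  }

  # K = 1: no mixture, sum of log item probabilities
  params1 <- random_params(1L, 3L, 9)
  X <- random_X(4L, 9)
  set.seed(10)
  Y <- matrix(sample(0:2, 12, replace = TRUE), 4L, 3L)
  direct <- sum(vapply(1:4, function(i) {
    sum(log(params1$rho[cbind(1:3, 1L, Y[i, ] + 1L)]))
  }, numeric(1)))
  expect_equal(lca_loglik(params1, matrices_to_ordinal(Y), covariates_for(X)),
               direct, tolerance = 1e-12)

  # beta = 0 gives uniform class probabilities
  params0 <- random_params(3L, 2L, 4)
  params0$beta[] <- 0
  lp <- dietlta:::class_logprobs(params0$beta, X[, , drop = FALSE], 3L)
  expect_equal(exp(lp), matrix(1 / 3, 4L, 3L), tolerance = 1e-12)
})

test_that("EM with one class reduces to observed category proportions", {
  set.seed(21)
  N <- 120L
  Y <- matrix(sample(0:2, N * 4L, TRUE, prob = c(0.5, 0.3, 0.2)), N, 4L)
  X <- random_X(N, 3)
  fit <- lca_em_fit(matrices_to_ordinal(Y), covariates_for(X), K = 1L,
                    n_starts = 1L, seed = 5L)
  for (j in 1:4) {
    expect_equal(unname(fit$params$rho[j, 1L, ]),
                 unname(table(factor(Y[, j], 0:2)) / N), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_equal(fit$n_params, 8L)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  for (r in 1:10) {
    set.seed(1000 + r)
    N <- 40L
    Y <- matrix(sample(0:2, N * 3L, TRUE), N, 3L)
    X <- random_X(N, 2000 + r)
    fit <- lca_em_fit(matrices_to_ordinal(Y), covariates_for(X), K = 2L,
                      n_starts = 1L, seed = r, max_iter = 60L)
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-length(tr)]))))
  }
})

test_that("EM finds the optimum a dense random parameter search cannot beat", {
  set.seed(33)
  N <- 6L
  Y <- matrix(sample(0:2, N * 2L, TRUE), N, 2L)
  X <- random_X(N, 12)
  ord <- matrices_to_ordinal(Y)
  cov <- covariates_for(X)
  fit <- lca_em_fit(ord, cov, K = 2L, n_starts = 10L, seed = 3L)
  best_random <- -Inf
  for (d in 1:10000) {
    cand <- random_params(2L, 2L, 50000 + d)
    best_random <- max(best_random, oracle_lca_loglik(cand, Y, X))
  }
  expect_gte(fit$loglik, best_random - 1e-6)
})

test_that("two-class structure is recovered from synthetic data", {
  cfg <- default_config(N = 1500L, J = 8L, K = 2L)
  pop <- generate_population(cfg, seed = 61)
  ord1 <- pop$ordinal[pop$ordinal$day == 1L, ]
  fit <- lca_em_fit(ord1, pop$covariates, K = 2L, n_starts = 4L, seed = 17L)
  pm <- dietlta:::match_classes(fit$params$rho, cfg$rho)
  mae <- mean(abs(fit$params$rho - cfg$rho[, pm, , drop = FALSE]))
  expect_lt(mae, 0.05)
  # membership-logit age effect recovered after the same alignment
  beta_true <- dietlta:::relabel_logit(cfg$beta1, pm, 2L)
  expect_lt(abs(fit$params$beta[1, "age"] - beta_true[1, 2]), 0.03)
})

test_that("posteriors are normalized, modal labels take the argmax, ties go low", {
  params <- random_params(3L, 2L, 77)
  X <- random_X(6L, 78)
  set.seed(79)
  Y <- matrix(sample(0:2, 12, TRUE), 6L, 2L)
  post <- lca_posterior(params, matrices_to_ordinal(Y), covariates_for(X))
  expect_equal(rowSums(post), rep(1, 6), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(classify_modal(post)),
               unname(apply(post, 1, which.max)), ignore_attr = TRUE)
  tied <- matrix(c(0.5, 0.5, 0.2, 0.5, 0.3, 0.5), 3L, 2L)
  tied <- cbind(tied, 1 - rowSums(tied))
  expect_message(lab <- classify_modal(rbind(c(0.5, 0.5, 0), c(0.2, 0.3, 0.5))),
                 "tied")
  expect_equal(as.integer(lab), c(1L, 3L))
  expect_equal(attr(lab, "ties"), 1L)

  # perfectly separating item responses give 0/1 posteriors
  sep <- list(K = 2L, rho = array(0, c(1L, 2L, 3L)),
              beta = matrix(0, 1L, 3L,
                            dimnames = list(NULL, c("(Intercept)", "age", "sex"))))
  sep$rho[1, 1, ] <- c(1, 0, 0)
  sep$rho[1, 2, ] <- c(0, 0, 1)
  Ysep <- matrix(c(0L, 2L, 0L, 2L), 4L, 1L)
  psep <- lca_posterior(sep, matrices_to_ordinal(Ysep), covariates_for(random_X(4L, 1)))
  expect_equal(unname(psep[, 1]), c(1, 0, 1, 0), tolerance = 1e-6)
})

test_that("class profile table is a weighted crosstab with rows summing to 100", {
  set.seed(90)
  Y <- matrix(sample(0:2, 20 * 2L, TRUE), 20L, 2L)
  ord <- matrices_to_ordinal(Y)
  labels <- rep(1:2, each = 10L)
  tab <- class_profile_table(ord, labels = labels)
  sums <- tapply(tab$percent, list(tab$class, tab$item), sum)
  expect_equal(unname(as.vector(sums)), rep(100, 4), tolerance = 1e-8)
  # hand crosstab for class 1, item 1
  hand <- 100 * table(factor(Y[1:10, 1L], 0:2)) / 10
  got <- tab$percent[tab$class == 1 & tab$item == "it01"]
  expect_equal(got, unname(as.vector(hand)), tolerance = 1e-10)
  # single class: table equals marginal percentages
  tab1 <- class_profile_table(ord, labels = rep(1L, 20L))
  marg <- 100 * table(factor(Y[, 2L], 0:2)) / 20
  expect_equal(tab1$percent[tab1$item == "it02"], unname(as.vector(marg)))
})

test_that("label permutation leaves the likelihood unchanged and covariates never hurt", {
  params <- random_params(3L, 3L, 55)
  X <- random_X(8L, 56)
  set.seed(57)
  Y <- matrix(sample(0:2, 24, TRUE), 8L, 3L)
  ord <- matrices_to_ordinal(Y)
  cov <- covariates_for(X)
  ll <- lca_loglik(params, ord, cov)
  perm <- c(2L, 3L, 1L)
  permuted <- list(K = 3L,
                   rho = params$rho[, perm, , drop = FALSE],
                   beta = dietlta:::relabel_logit(params$beta, perm, 3L))
  expect_equal(lca_loglik(permuted, ord, cov), ll, tolerance = 1e-10)

  # intercept-only logit is nested in the covariate model
  cfgn <- default_config(N = 300L, J = 6L, K = 2L)
  popn <- generate_population(cfgn, seed = 58)
  ordb <- popn$ordinal[popn$ordinal$day == 1L, ]
  covb <- popn$covariates
  fit_cov <- lca_em_fit(ordb, covb, K = 2L, n_starts = 5L, seed = 7L)
  cov0 <- covb
  cov0$age <- 50
  cov0$sex <- 0
  fit_null <- lca_em_fit(ordb, cov0, K = 2L, n_starts = 5L, seed = 7L)
  expect_gte(fit_cov$loglik, fit_null$loglik - 1e-6)
})
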