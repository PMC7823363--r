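test_that("transition-model log-likelihood matches exhaustive path enumeration", {
  for (seed in 1:5) {
    K <- sample(2:3, 1)
    params <- random_params(K, 2L, seed, lta = TRUE)
    X <- random_X(3L, seed + 10)
    set.seed(seed + 20)
    Y1 <- matrix(sample(0:2, 6, TRUE), 3L, 2L)
    Y2 <- matrix(sample(0:2, 6, TRUE), 3L, 2L)
    ll <- lta_loglik(params, matrices_to_ordinal(Y1, Y2), covariates_for(X))
    expect_equal(ll, oracle_lta_loglik(params, Y1, Y2, X), tolerance = 1e-12)
  }

  # K = 1: both days contribute their item log-probabilities
  params1 <- random_params(1L, 3L, 31, lta = TRUE)
  X <- random_X(4L, 32)
  set.seed(33)
  Y1 <- matrix(sample(0:2, 12, TRUE), 4L, 3L)
  Y2 <- matrix(sample(0:2, 12, TRUE), 4L, 3L)
  direct <- sum(log(params1$rho[cbind(rep(1:3, 4), 1L, as.vector(t(Y1 + 1L)))])) +
    sum(log(params1$rho[cbind(rep(1:3, 4), 1L, as.vector(t(Y2 + 1L)))]))
  expect_equal(lta_loglik(params1, matrices_to_ordinal(Y1, Y2),
                          covariates_for(X)),
               direct, tolerance = 1e-12)
})

test_that("an identity transition matrix reduces the model to a shared-class two-day LCA", {
  K <- 2L
  params <- random_params(K, 2L, 44, lta = TRUE)
  params$trans_a <- matrix(c(60, -60), 2L, 1L)  # diagonal ~ 1
  params$gamma[] <- 0
  X <- random_X(5L, 45)
  set.seed(46)
  Y1 <- matrix(sample(0:2, 10, TRUE), 5L, 2L)
  Y2 <- matrix(sample(0:2, 10, TRUE), 5L, 2L)
  ll_lta <- lta_loglik(params, matrices_to_ordinal(Y1, Y2), covariates_for(X))
  # stacked responses with one shared class: emission over both days
  lca_params <- list(K = K, rho = params$rho, beta = params$beta1)
  ll_shared <- sum(vapply(1:5, function(i) {
    pri <- oracle_class_probs(params$beta1, X[i, ], K)
    log(sum(vapply(1:K, function(k) {
      pri[k] * prod(params$rho[cbind(1:2, k, Y1[i, ] + 1L)]) *
        prod(params$rho[cbind(1:2, k, Y2[i, ] + 1L)])
    }, numeric(1))))
  }, numeric(1)))
  expect_equal(ll_lta, ll_shared, tolerance = 1e-8)
})

test_that("EM log-likelihood is non-decreasing and invariance holds by construction", {
  for (r in 1:10) {
    set.seed(3000 + r)
    N <- 30L
    Y1 <- matrix(sample(0:2, N * 3L, TRUE), N, 3L)
    Y2 <- matrix(sample(0:2, N * 3L, TRUE), N, 3L)
    X <- random_X(N, 4000 + r)
    fit <- lta_em_fit(matrices_to_ordinal(Y1, Y2), covariates_for(X), K = 2L,
                      n_starts = 1L, seed = r, max_iter = 50L)
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-length(tr)]))))
  }
})

test_that("joint posteriors are coherent and measurement invariance is structural", {
  cfg <- default_config(N = 300L, J = 6L)
  pop <- generate_population(cfg, seed = 5)
  fit <- lta_em_fit(pop$ordinal, pop$covariates, K = 2L, n_starts = 2L,
                    seed = 9L, max_iter = 150L)
  q <- fit$joint_posterior
  expect_equal(apply(q, 1L, sum), rep(1, fit$N), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(apply(q, c(1L, 2L), sum), unname(fit$posterior),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(apply(q, c(1L, 3L), sum), unname(fit$posterior_day2),
               tolerance = 1e-10, ignore_attr = TRUE)
  # one rho object serves both days (measurement invariance): the public
  # likelihood evaluated with that single array reproduces the fit
  expect_equal(dim(fit$params$rho), c(6L, 2L, 3L))
  # reported loglik equals the public likelihood at the fitted params
  # (evaluated with the floored rho actually used during EM)
  pint <- fit$params
  pint$rho <- fit$rho_internal
  ll <- lta_loglik(pint, pop$ordinal, pop$covariates)
  expect_equal(ll, fit$loglik, tolerance = 1e-8)
})

test_that("a verbatim day-2 copy concentrates transitions on the diagonal", {
  cfg <- default_config(N = 400L, J = 8L)
  pop <- generate_population(cfg, seed = 14)
  ord <- pop$ordinal
  d1 <- ord[ord$day == 1L, ]
  d2 <- d1
  d2$day <- 2L
  fit <- lta_em_fit(rbind(d1, d2), pop$covariates, K = 2L, n_starts = 2L,
                    seed = 3L, max_iter = 200L)
  P <- aggregate_transition_matrix(fit)
  expect_gt(min(diag(P)), 0.95)
})

test_that("constraining the covariate effects can only lower the maximized likelihood", {
  cfg <- default_config(N = 400L, J = 6L)
  pop <- generate_population(cfg, seed = 23)
  fit_c <- lta_em_fit(pop$ordinal, pop$covariates, K = 2L, n_starts = 3L,
                      seed = 11L, max_iter = 200L, constrain_covariates = TRUE)
  fit_u <- lta_em_fit(pop$ordinal, pop$covariates, K = 2L, n_starts = 3L,
                      seed = 11L, max_iter = 200L, constrain_covariates = FALSE)
  expect_lte(fit_c$loglik, fit_u$loglik + 1e-4)
  expect_equal(fit_u$n_params - fit_c$n_params, (2L - 1L) * 2L)
  # constrained fit reports gamma equal to the beta1 covariate block
  expect_equal(unname(fit_c$params$gamma),
               unname(fit_c$params$beta1[, -1L, drop = FALSE]))
})

test_that("covariate-conditional transition matrices are proper and monotone", {
  params <- random_params(3L, 2L, 71, lta = TRUE)
  # zero parameters -> uniform rows
  p0 <- params
  p0$trans_a[] <- 0
  p0$gamma[] <- 0
  P <- transition_matrix(p0, c(age = 40, sex = 1))
  expect_equal(unname(P), matrix(1 / 3, 3L, 3L), tolerance = 1e-12)
  # rows sum to 1 for random parameter draws
  for (d in 1:50) {
    pr <- random_params(sample(2:4, 1), 2L, 9000 + d, lta = TRUE)
    Pd <- transition_matrix(pr, c(age = runif(1, 18, 84), sex = rbinom(1, 1, 0.5)))
    expect_equal(rowSums(Pd), rep(1, pr$K), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # a positive age slope toward destination 1 makes that probability increase
  pm <- params
  pm$gamma[] <- 0
  pm$gamma[1, 1] <- 0.08
  ages <- seq(20, 80, by = 5)
  probs <- vapply(ages, function(a) {
    transition_matrix(pm, c(age = a, sex = 0))[2, 1]
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("the aggregate transition matrix is the posterior-weighted row average", {
  params <- random_params(2L, 2L, 83, lta = TRUE)
  # two covariate subgroups with hand-computed weighted mean
  X <- cbind(age = c(30, 30, 70, 70), sex = c(0, 0, 1, 1))
  w <- matrix(c(0.8, 0.2,
                0.6, 0.4,
                0.3, 0.7,
                0.1, 0.9), 4L, 2L, byrow = TRUE)
  fit_stub <- structure(list(params = params, X = X, posterior = w),
                        class = "lta_fit")
  P <- aggregate_transition_matrix(fit_stub)
  Pi <- lapply(1:4, function(i) transition_matrix(params, X[i, ]))
  for (k in 1:2) {
    hand <- Reduce(`+`, lapply(1:4, function(i) w[i, k] * Pi[[i]][k, ]))
    hand <- hand / sum(w[, k])
    expect_equal(unname(P[k, ]), unname(hand), tolerance = 1e-10)
  }
  expect_equal(rowSums(P), rep(1, 2), tolerance = 1e-10, ignore_attr = TRUE)
  # identical covariates: aggregate equals the single-covariate matrix
  X1 <- cbind(age = rep(50, 3), sex = rep(1, 3))
  fit_one <- structure(list(params = params, X = X1,
                            posterior = matrix(1 / 2, 3L, 2L)),
                       class = "lta_fit")
  expect_equal(unname(aggregate_transition_matrix(fit_one)),
               unname(transition_matrix(params, c(age = 50, sex = 1))),
               tolerance = 1e-12)
})

test_that("parameter counts match the packed free-parameter dimension", {
  expect_equal(count_params("lca", K = 1L, J = 5L), 10L)
  expect_equal(count_params("lca", K = 6L, J = 28L), 28L * 6L * 2L + 5L * 3L)
  expect_equal(count_params("lta", K = 3L, J = 28L, constrained = TRUE),
               28L * 3L * 2L + 2L * 3L + 3L * 2L)
  expect_equal(count_params("lta", K = 3L, J = 28L, constrained = FALSE) -
                 count_params("lta", K = 3L, J = 28L, constrained = TRUE),
               2L * 2L)
  # introspection: packed vector length equals the reported count minus
  # the rho block expressed as free logits
  params <- random_params(3L, 10L, 91, lta = TRUE)
  params$constrained <- FALSE
  th <- dietlta:::pack_lta(params)
  expect_equal(length(th),
               count_params("lta", K = 3L, J = 10L, constrained = FALSE))
  params$constrained <- TRUE
  expect_equal(length(dietlta:::pack_lta(params)),
               count_params("lta", K = 3L, J = 10L, constrained = TRUE))
  # round trip through the packing used for observed information
  back <- dietlta:::unpack_lta(th, params)
  expect_equal(back$rho, params$rho, tolerance = 1e-6)
  expect_equal(unname(back$beta1), unname(params$beta1), tolerance = 1e-10)
  expect_equal(back$trans_a, params$trans_a, tolerance = 1e-10)
})

test_that("odds ratios expose the membership logit with sane signs and intervals", {
  cfg <- default_config(N = 500L, J = 6L, K = 2L)
  pop <- generate_population(cfg, seed = 51)
  fit <- lta_em_fit(pop$ordinal, pop$covariates, K = 2L, n_starts = 2L,
                    seed = 13L, max_iter = 300L)
  ors <- membership_odds_ratios(fit)
  expect_setequal(ors$covariate, c("age", "sex"))
  expect_equal(ors$or, exp(ors$estimate), tolerance = 1e-12)
  expect_true(all(ors$ci_lower < ors$or & ors$or < ors$ci_upper))
  # negative coefficient <=> OR below 1
  expect_true(all((ors$estimate < 0) == (ors$or < 1)))
  zero_fit <- fit
  zero_fit$params$beta1[1, "age"] <- 0
  ors0 <- membership_odds_ratios(zero_fit)
  expect_equal(ors0$or[ors0$covariate == "age"], 1)

  # bootstrap route returns the same point estimates with finite intervals
  cfg_s <- default_config(N = 120L, J = 4L, K = 2L)
  pop_s <- generate_population(cfg_s, seed = 77)
  fit_s <- lta_em_fit(pop_s$ordinal, pop_s$covariates, K = 2L,
                      n_starts = 1L, seed = 2L, max_iter = 150L)
  orb <- membership_odds_ratios(fit_s, method = "bootstrap", n_boot = 6L,
                                n_starts_boot = 1L)
  expect_equal(orb$method, rep("bootstrap", 2L))
  expect_equal(orb$or, exp(orb$estimate))
  expect_true(all(is.finite(orb$ci_lower) & is.finite(orb$ci_upper)))
})
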