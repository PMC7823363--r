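#' Configuration for the synthetic two-day recall generator
#'
#' Defines a cohort with the statistical structure the models assume:
#' covariates age (uniform over `age_range`) and sex (Bernoulli with
#' `male_prop`), day-1 class from a multinomial logit on the covariates,
#' day-2 class from a covariate-conditional transition logit, and
#' class-conditional item responses identical on both days
#' (measurement invariance). An optional continuous layer generates
#' gram amounts instead of categories: per (item, class) a consumption
#' probability and a gamma amount distribution, so zero inflation and
#' realistic day-to-day variability arise and the median-based ordinal
#' coding is exercised rather than bypassed.
#'
#' @param N subjects; @param K classes; @param J items.
#' @param rho J x K x 3 item-response probability array.
#' @param beta1 (K-1) x 3 day-1 membership logit (intercept, age, sex),
#'   age in years, reference class K.
#' @param trans_a K x (K-1) transition intercepts.
#' @param gamma (K-1) x 2 destination covariate slopes (age, sex);
#'   defaults to the covariate block of `beta1` (effects shared across
#'   days).
#' @param age_range,male_prop covariate distribution (defaults 18-84,
#'   0.473 men).
#' @param continuous optional list with `consume_prob` (J x K),
#'   `shape`, `scale` (J x K gamma parameters), `subject_sd` (length-J
#'   log-normal SDs of a per-subject intake level held fixed across
#'   days) and `consume_icc` (length-J probit correlations of the
#'   day-1/day-2 consumption indicators). Together these let items span
#'   a realistic range of day-to-day intra-class correlations while
#'   keeping the marginal nil fractions at their targets.
#' @return a `generator_config` list.
#' @export
generator_config <- function(N, K, J, rho, beta1, trans_a,
                             gamma = NULL, age_range = c(18, 84),
                             male_prop = 0.473, continuous = NULL) {
  stopifnot(dim(rho)[1] == J, dim(rho)[2] == K, dim(rho)[3] == 3L)
  if (max(abs(apply(rho, c(1, 2), sum) - 1)) > 1e-8) {
    stop("rho rows must sum to 1 over categories")
  }
  if (K > 1L) {
    stopifnot(nrow(beta1) == K - 1L, ncol(beta1) == 3L,
              nrow(trans_a) == K, ncol(trans_a) == K - 1L)
  }
  if (is.null(gamma)) {
    gamma <- if (K > 1L) beta1[, -1L, drop = FALSE] else
      matrix(numeric(0), 0L, 2L)
  }
  structure(list(N = N, K = K, J = J, rho = rho, beta1 = beta1,
                 trans_a = trans_a, gamma = gamma, age_range = age_range,
                 male_prop = male_prop, continuous = continuous),
            class = "generator_config")
}

#' A realistic default configuration
#'
#' Three patterns over 28 food groups with nil fractions spanning about
#' 10-95%, age effects negative and male effects positive for the two
#' less-healthy patterns against the reference (so older women
#' concentrate in the reference, healthier-like pattern), and
#' transition intercepts giving strong but imperfect day-to-day
#' stability. Intended for demonstrations and end-to-end checks with
#' known truth; it emulates the qualitative structure of national
#' two-day recall data without claiming any survey's numbers.
#'
#' @param N cohort size (default 3000).
#' @param J number of food groups (default 28).
#' @param K number of classes (default 3).
#' @param continuous generate a gram-amount layer (default FALSE).
#' @param seed seed for drawing the fixed item-response truth.
#' @return a `generator_config`.
#' @export
default_config <- function(N = 3000L, J = 28L, K = 3L,
                           continuous = FALSE, seed = 2026L) {
  set.seed(seed)
  # class-separated item responses: each item leans toward a different
  # category in each class, with nil propensity varying across items
  rho <- array(0, dim = c(J, K, 3L))
  nil_base <- seq(0.10, 0.80, length.out = J)
  for (j in seq_len(J)) {
    lead <- (j %% K) + 1L
    for (k in seq_len(K)) {
      nil <- min(0.9, max(0.02, nil_base[j] + ifelse(k == lead, -0.25, 0.15)))
      pos <- 1 - nil
      hi <- if (k == lead) 0.75 else 0.3
      rho[j, k, ] <- c(nil, pos * (1 - hi), pos * hi)
    }
  }
  # covariate effects on the log-odds scale: per-year age effects and a
  # male effect pushing toward the non-reference (less healthy-like)
  # patterns, echoing typical recall-survey findings
  slope_pool <- matrix(c(-0.052, 1.81,
                         -0.083, 1.82,
                         -0.030, 0.90,
                         -0.020, 0.60,
                         -0.010, 0.40,
                         -0.005, 0.20), ncol = 2L, byrow = TRUE)
  slopes <- slope_pool[seq_len(K - 1L), , drop = FALSE]
  xbar <- c(age = mean(c(18, 84)), sex = 0.473)
  # intercepts pinned so that day-1 class shares at the covariate mean
  # are moderately unbalanced, largest class first
  s1_target <- if (K == 3L) c(0.40, 0.27, 0.33) else {
    v <- rev(seq_len(K)); v / sum(v)
  }
  beta1 <- cbind(log(s1_target[-K] / s1_target[K]) -
                   as.vector(slopes %*% xbar), slopes)
  colnames(beta1) <- c("(Intercept)", "age", "sex")
  # transition intercepts chosen so that at the covariate mean the
  # diagonal dominates (high day-to-day pattern stability)
  gamma <- beta1[, -1L, drop = FALSE]
  target <- matrix(c(0.85, 0.10, 0.05,
                     0.12, 0.80, 0.08,
                     0.04, 0.06, 0.90), 3L, 3L, byrow = TRUE)
  if (K != 3L) {
    target <- matrix(0.1 / (K - 1), K, K)
    diag(target) <- 0.9
  }
  trans_a <- matrix(0, K, K - 1L)
  for (k in seq_len(K)) {
    trans_a[k, ] <- log(target[k, -K] / target[k, K]) -
      as.vector(gamma %*% xbar)
  }
  cont <- NULL
  if (continuous) {
    consume_prob <- 1 - rho[, , 1L]
    # day-level amount noise shrinking along the item list
    shape <- matrix(rep(seq(1.5, 15, length.out = J), K), J, K)
    # class-specific mean amounts so the >median category tracks class
    scale <- matrix(rep(seq(20, 120, length.out = J), K), J, K)
    scale <- scale * matrix(runif(J * K, 0.7, 1.4), J, K)
    # stable per-person intake levels and habit-persistent consumption,
    # of varying strength, so items span a spread of day-to-day
    # intra-class correlations comparable to repeated recall data
    subject_sd <- seq(0.15, 1.1, length.out = J)
    consume_icc <- seq(0.1, 0.95, length.out = J)
    cont <- list(consume_prob = consume_prob, shape = shape, scale = scale,
                 subject_sd = subject_sd, consume_icc = consume_icc)
  }
  generator_config(N = N, K = K, J = J, rho = rho, beta1 = beta1,
                   trans_a = trans_a, gamma = gamma, continuous = cont)
}

#' Generate a synthetic cohort with known latent truth
#'
#' Draws covariates, latent day-1 and day-2 classes, and either ordinal
#' categories directly from `rho` or gram amounts from the continuous
#' layer (to be coded by [categorize_intake()]). Fully reproducible
#' from the seed.
#'
#' @param config a `generator_config`.
#' @param seed master seed.
#' @return list with `covariates`, `truth` (data.frame `subject_id`,
#'   `class_day1`, `class_day2`), `ordinal` (when categorical), and
#'   `intake` (when the continuous layer is configured).
#' @export
generate_population <- function(config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  N <- config$N; K <- config$K; J <- config$J
  ids <- sprintf("S%05d", seq_len(N))
  age <- stats::runif(N, config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(N, 1L, config$male_prop)
  X <- cbind(age = age, sex = sex)
  pi1 <- exp(class_logprobs(config$beta1, X, K))
  c1 <- vapply(seq_len(N), function(i) sample.int(K, 1L, prob = pi1[i, ]),
               integer(1))
  Pt <- subject_transitions(list(trans_a = config$trans_a,
                                 gamma = config$gamma, K = K), X)
  c2 <- vapply(seq_len(N), function(i) {
    sample.int(K, 1L, prob = Pt[i, c1[i], ])
  }, integer(1))
  covariates <- data.frame(subject_id = ids, age = age, sex = sex,
                           stringsAsFactors = FALSE)
  truth <- data.frame(subject_id = ids, class_day1 = c1, class_day2 = c2,
                      stringsAsFactors = FALSE)
  items <- sprintf("fg%02d", seq_len(J))
  out <- list(covariates = covariates, truth = truth, config = config)

  if (is.null(config$continuous)) {
    draw_day <- function(cl) {
      cat <- matrix(0L, N, J)
      for (j in seq_len(J)) {
        u <- stats::runif(N)
        cum1 <- config$rho[j, cl, 1L]
        cum2 <- cum1 + config$rho[j, cl, 2L]
        cat[, j] <- ifelse(u < cum1, 0L, ifelse(u < cum2, 1L, 2L))
      }
      cat
    }
    Y1 <- draw_day(c1)
    Y2 <- draw_day(c2)
    ordinal <- rbind(
      data.frame(subject_id = rep(ids, J), day = 1L,
                 item = rep(items, each = N), category = as.vector(Y1)),
      data.frame(subject_id = rep(ids, J), day = 2L,
                 item = rep(items, each = N), category = as.vector(Y2)))
    out$ordinal <- ordinal[order(ordinal$subject_id, ordinal$day,
                                 ordinal$item), ]
  } else {
    cl_layer <- config$continuous
    sd_j <- cl_layer$subject_sd %||% rep(0, J)
    r_j <- cl_layer$consume_icc %||% rep(0, J)
    # per-subject multiplicative intake level, constant across days
    # (mean-one log-normal)
    level <- vapply(seq_len(J), function(j) {
      exp(stats::rnorm(N, -sd_j[j]^2 / 2, sd_j[j]))
    }, numeric(N))
    # habit persistence: consumption indicators correlated across days
    # through a shared probit factor; marginal rates stay at consume_prob
    z_shared <- matrix(stats::rnorm(N * J), N, J)
    draw_amounts <- function(cl) {
      A <- matrix(0, N, J)
      for (j in seq_len(J)) {
        pcons <- cl_layer$consume_prob[j, cl]
        z_day <- sqrt(r_j[j]) * z_shared[, j] +
          sqrt(1 - r_j[j]) * stats::rnorm(N)
        eats <- z_day < stats::qnorm(pcons)
        A[eats, j] <- level[eats, j] *
          stats::rgamma(sum(eats),
                        shape = cl_layer$shape[j, cl[eats]],
                        scale = cl_layer$scale[j, cl[eats]])
      }
      A
    }
    A1 <- draw_amounts(c1)
    A2 <- draw_amounts(c2)
    intake <- rbind(
      data.frame(subject_id = rep(ids, J), day = 1L,
                 food_group = rep(items, each = N), amount = as.vector(A1)),
      data.frame(subject_id = rep(ids, J), day = 2L,
                 food_group = rep(items, each = N), amount = as.vector(A2)))
    out$intake <- intake[order(intake$subject_id, intake$day,
                               intake$food_group), ]
  }
  out
}

#' True covariate-averaged usual prevalence of a generator
#'
#' The stationary vector of the covariate-conditional true transition
#' matrix, integrated numerically over the generator's covariate
#' distribution (a fine uniform age grid crossed with the two sexes at
#' their configured proportions). This is the target that usual-
#' prevalence recovery is judged against.
#'
#' @param config a `generator_config`.
#' @param n_age_grid number of age quadrature points (default 201).
#' @return probability vector of length K.
#' @export
true_usual_prevalence <- function(config, n_age_grid = 201L) {
  K <- config$K
  if (K == 1L) return(1)
  ages <- seq(config$age_range[1], config$age_range[2],
              length.out = n_age_grid)
  # trapezoid weights on the uniform age density
  w_age <- rep(1, n_age_grid)
  w_age[c(1L, n_age_grid)] <- 0.5
  w_age <- w_age / sum(w_age)
  acc <- rep(0, K)
  for (sx in c(0, 1)) {
    w_sex <- if (sx == 1) config$male_prop else 1 - config$male_prop
    X <- cbind(age = ages, sex = sx)
    Pt <- subject_transitions(list(trans_a = config$trans_a,
                                   gamma = config$gamma, K = K), X)
    for (i in seq_len(n_age_grid)) {
      P <- matrix(Pt[i, , ], K, K)
      if (any(P <= 0)) {
        reg <- is_regular(P)
        if (!reg$regular) stop("true transition matrix not regular at age ",
                               ages[i], ", sex ", sx)
      }
      acc <- acc + w_sex * w_age[i] * stationary_solve(P)
    }
  }
  acc / sum(acc)
}
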