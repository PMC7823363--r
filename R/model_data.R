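# Internal: convert an ordinal table + covariates into the dense
# matrices the EM routines operate on.
#
# Returns list(subjects, items, Y: list of N x J integer matrices
# (categories 0..C-1), one per day present, X: N x p covariate matrix
# (age, sex) aligned to `subjects`, C: number of categories).
build_model_data <- function(ordinal, covariates, days = NULL) {
  needed <- c("subject_id", "day", "item", "category")
  miss <- setdiff(needed, names(ordinal))
  if (length(miss)) {
    stop("ordinal table is missing column(s): ", paste(miss, collapse = ", "))
  }
  covariates <- validate_covariates(covariates)
  subjects <- sort(unique(ordinal$subject_id))
  items <- sort(unique(ordinal$item))
  if (is.null(days)) days <- sort(unique(ordinal$day))
  if (!all(subjects %in% covariates$subject_id)) {
    stop("covariate table lacks rows for some subjects in the ordinal table")
  }
  ci <- match(subjects, covariates$subject_id)
  X <- cbind(age = covariates$age[ci], sex = covariates$sex[ci])
  rownames(X) <- subjects
  N <- length(subjects)
  J <- length(items)
  Y <- lapply(days, function(d) {
    sub <- ordinal[ordinal$day == d, ]
    M <- matrix(NA_integer_, N, J, dimnames = list(subjects, items))
    M[cbind(match(sub$subject_id, subjects), match(sub$item, items))] <-
      as.integer(sub$category)
    if (anyNA(M)) {
      stop("ordinal table incomplete on day ", d,
           ": every (subject, item) cell is required")
    }
    M
  })
  names(Y) <- paste0("day", days)
  C <- max(vapply(Y, max, integer(1))) + 1L
  if (C < 3L) C <- 3L
  if (any(vapply(Y, min, integer(1)) < 0L) || C > 3L) {
    stop("categories must lie in {0, 1, 2}")
  }
  list(subjects = subjects, items = items, Y = Y, X = X, C = C,
       N = N, J = J, days = days)
}

# Emission log-likelihood matrix: L[i, k] = sum_j log rho[j, k, Y[i, j] + 1].
emission_loglik <- function(logrho, Ymat) {
  N <- nrow(Ymat)
  J <- ncol(Ymat)
  K <- dim(logrho)[2]
  L <- matrix(0, N, K)
  for (k in seq_len(K)) {
    acc <- numeric(N)
    for (j in seq_len(J)) {
      acc <- acc + logrho[j, k, Ymat[, j] + 1L]
    }
    L[, k] <- acc
  }
  L
}

# Standardize age for optimizer stability; returns the design pieces and
# the transform needed to report coefficients back on the years scale.
standardize_covariates <- function(X) {
  mu <- mean(X[, "age"])
  sd_age <- stats::sd(X[, "age"])
  if (!is.finite(sd_age) || sd_age == 0) sd_age <- 1
  Xs <- X
  Xs[, "age"] <- (X[, "age"] - mu) / sd_age
  list(Xs = Xs, age_mean = mu, age_sd = sd_age)
}

# Map logit coefficients fitted on standardized age back to years.
# B has columns (intercept, age, sex, ...).
unstandardize_beta <- function(B, age_mean, age_sd) {
  if (is.null(B) || nrow(B) == 0L) return(B)
  out <- B
  out[, "age"] <- B[, "age"] / age_sd
  out[, "(Intercept)"] <- B[, "(Intercept)"] - B[, "age"] * age_mean / age_sd
  out
}

# The reverse map, used when evaluating a reported-scale model internally.
standardize_beta <- function(B, age_mean, age_sd) {
  if (is.null(B) || nrow(B) == 0L) return(B)
  out <- B
  out[, "age"] <- B[, "age"] * age_sd
  out[, "(Intercept)"] <- B[, "(Intercept)"] + B[, "age"] * age_mean / age_sd
  out
}
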