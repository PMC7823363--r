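# Packed-parameter representation of an LTA fit on an unconstrained
# scale, used for observed-information standard errors.  rho is mapped
# to per-(item, class) multinomial logits against the last category;
# the logit blocks enter as-is (raw covariate scale).
pack_lta <- function(params) {
  K <- params$K
  C <- dim(params$rho)[3]
  rr <- pmax(params$rho, 1e-8)
  z <- log(rr[, , -C, drop = FALSE] /
             as.vector(rr[, , C]))
  th <- c(as.vector(z), as.vector(params$beta1), as.vector(params$trans_a))
  if (!isTRUE(params$constrained)) th <- c(th, as.vector(params$gamma))
  th
}

unpack_lta <- function(th, template) {
  K <- template$K
  J <- dim(template$rho)[1]
  C <- dim(template$rho)[3]
  p <- ncol(template$gamma)
  n_z <- J * K * (C - 1L)
  z <- array(th[seq_len(n_z)], dim = c(J, K, C - 1L))
  e <- array(0, dim = c(J, K, C))
  e[, , seq_len(C - 1L)] <- exp(z)
  e[, , C] <- 1
  sw <- apply(e, c(1L, 2L), sum)
  rho <- e
  for (cc in seq_len(C)) rho[, , cc] <- e[, , cc] / sw
  i <- n_z
  n_b <- (K - 1L) * (1L + p)
  beta1 <- matrix(th[i + seq_len(n_b)], K - 1L, 1L + p,
                  dimnames = dimnames(template$beta1))
  i <- i + n_b
  n_a <- K * (K - 1L)
  trans_a <- matrix(th[i + seq_len(n_a)], K, K - 1L)
  i <- i + n_a
  gamma <- if (isTRUE(template$constrained)) {
    beta1[, -1L, drop = FALSE]
  } else {
    matrix(th[i + seq_len((K - 1L) * p)], K - 1L, p)
  }
  list(K = K, rho = rho, beta1 = beta1, trans_a = trans_a, gamma = gamma,
       constrained = template$constrained)
}

#' Odds ratios for day-1 pattern membership
#'
#' Exponentiated coefficients of the day-1 membership logit (each class
#' against the reference class `K`), with Wald confidence intervals from
#' the observed information matrix -- the full log-likelihood Hessian at
#' the optimum, obtained by numerical differentiation over all free
#' parameters. If the information matrix is singular (or yields
#' non-positive variances), a nonparametric bootstrap is used instead,
#' with a warning.
#'
#' @param fit `lta_fit` object.
#' @param method `"observed"` information (default) or `"bootstrap"`.
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap replicates for the fallback (default 200).
#' @param boot_seed seed for the bootstrap resampling.
#' @param n_starts_boot EM starts per bootstrap refit.
#' @return data.frame `class`, `covariate`, `estimate` (log-odds), `or`,
#'   `se`, `ci_lower`, `ci_upper`, `method`.
#' @export
membership_odds_ratios <- function(fit, method = c("observed", "bootstrap"),
                                   level = 0.95, n_boot = 200L,
                                   boot_seed = 1L, n_starts_boot = 2L) {
  method <- match.arg(method)
  params <- fit$params
  K <- params$K
  if (K == 1L) stop("odds ratios need at least two classes")
  covs <- colnames(params$beta1)[-1L]
  est <- params$beta1[, covs, drop = FALSE]
  z <- stats::qnorm(1 - (1 - level) / 2)

  if (method == "observed") {
    th <- pack_lta(params)
    negll <- function(t) {
      -lta_loglik_mat(unpack_lta(t, params), fit$Y1, fit$Y2, fit$X,
                      prob_floor = 1e-12)
    }
    H <- num_hessian(negll, th)
    V <- try(solve(H), silent = TRUE)
    n_z <- length(params$rho) / dim(params$rho)[3] * (dim(params$rho)[3] - 1L)
    ok <- !inherits(V, "try-error") && all(is.finite(diag(V)))
    if (ok) {
      # indices of beta1 inside the packed vector (column-major)
      idx_beta <- n_z + seq_len(length(params$beta1))
      vb <- diag(V)[idx_beta]
      se_beta <- matrix(ifelse(vb > 0, sqrt(vb), NA_real_), K - 1L,
                        ncol(params$beta1))
      colnames(se_beta) <- colnames(params$beta1)
      se <- se_beta[, covs, drop = FALSE]
      ok <- all(is.finite(se))
    }
    if (!ok) {
      warning("observed information matrix singular or indefinite; ",
              "falling back to the nonparametric bootstrap")
      return(membership_odds_ratios(fit, method = "bootstrap",
                                    level = level, n_boot = n_boot,
                                    boot_seed = boot_seed,
                                    n_starts_boot = n_starts_boot))
    }
    out <- expand.grid(class = seq_len(K - 1L), covariate = covs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$estimate <- as.vector(est)
    out$se <- as.vector(se)
    out$or <- exp(out$estimate)
    out$ci_lower <- exp(out$estimate - z * out$se)
    out$ci_upper <- exp(out$estimate + z * out$se)
    out$method <- "observed"
    return(out)
  }

  # nonparametric bootstrap: resample subjects, refit, align classes to
  # the original solution by item-response profiles
  set.seed(boot_seed)
  N <- fit$N
  boots <- array(NA_real_, dim = c(n_boot, K - 1L, length(covs)))
  ordinal <- rbind(
    data.frame(subject_id = rep(rownames(fit$Y1), ncol(fit$Y1)),
               day = 1L, item = rep(colnames(fit$Y1), each = nrow(fit$Y1)),
               category = as.vector(fit$Y1)),
    data.frame(subject_id = rep(rownames(fit$Y2), ncol(fit$Y2)),
               day = 2L, item = rep(colnames(fit$Y2), each = nrow(fit$Y2)),
               category = as.vector(fit$Y2)))
  covariates <- data.frame(subject_id = rownames(fit$X),
                           age = fit$X[, "age"], sex = fit$X[, "sex"])
  for (b in seq_len(n_boot)) {
    ids <- sample.int(N, N, replace = TRUE)
    newid <- sprintf("b%06d", seq_len(N))
    ord_b <- do.call(rbind, lapply(seq_len(N), function(i) {
      o <- ordinal[ordinal$subject_id == rownames(fit$X)[ids[i]], ]
      o$subject_id <- newid[i]
      o
    }))
    cov_b <- data.frame(subject_id = newid,
                        age = covariates$age[ids], sex = covariates$sex[ids])
    fb <- try(lta_em_fit(ord_b, cov_b, K = K, n_starts = n_starts_boot,
                         seed = b, constrain_covariates = params$constrained),
              silent = TRUE)
    if (inherits(fb, "try-error")) next
    pm <- match_classes(params$rho, fb$params$rho)
    bperm <- relabel_logit(fb$params$beta1, pm, K)
    colnames(bperm) <- colnames(fb$params$beta1)
    boots[b, , ] <- bperm[, covs, drop = FALSE]
  }
  qs <- apply(boots, c(2L, 3L), stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  ses <- apply(boots, c(2L, 3L), stats::sd, na.rm = TRUE)
  out <- expand.grid(class = seq_len(K - 1L), covariate = covs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$estimate <- as.vector(est)
  out$se <- as.vector(ses)
  out$or <- exp(out$estimate)
  out$ci_lower <- exp(as.vector(qs[1L, , ]))
  out$ci_upper <- exp(as.vector(qs[2L, , ]))
  out$method <- "bootstrap"
  out
}
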