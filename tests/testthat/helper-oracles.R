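# Independent small-instance oracles for the mixed models: direct
# optimizers of the exact marginal (restricted) likelihood, written against
# dense matrices and generic optimizers only.

# Exact REML fit of y = X beta + u[participant] + e by direct optimization
# of the restricted log-likelihood over (log tau2, log sigma2).
reml_oracle <- function(y, X, participant) {
  n <- length(y)
  Z <- stats::model.matrix(~ 0 + factor(participant))
  neg2_reml <- function(par) {
    tau2 <- exp(par[1]); sigma2 <- exp(par[2])
    V <- sigma2 * diag(n) + tau2 * tcrossprod(Z)
    cV <- chol(V)
    Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
    Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(X, Vi_y))
    r <- y - X %*% beta
    Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
    2 * sum(log(diag(cV))) + determinant(XtViX)$modulus +
      drop(crossprod(r, Vi_r))
  }
  opt <- stats::optim(c(log(0.01), log(0.01)), neg2_reml,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  tau2 <- exp(opt$par[1]); sigma2 <- exp(opt$par[2])
  V <- sigma2 * diag(n) + tau2 * tcrossprod(Z)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  list(beta = drop(beta), tau2 = tau2, sigma2 = sigma2)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (weight exp(-x^2)).
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Direct maximizer of the exact marginal likelihood of a random-intercept
# logistic model, integrating the intercept by fixed Gauss-Hermite rules.
glmm_oracle <- function(y, X, participant, n_nodes = 40) {
  gh <- gauss_hermite(n_nodes)
  ids <- unique(participant)
  neg_loglik <- function(par) {
    beta <- par[-length(par)]
    tau <- exp(par[length(par)])
    eta0 <- drop(X %*% beta)
    ll <- 0
    for (id in ids) {
      sel <- participant == id
      li <- vapply(seq_along(gh$nodes), function(k) {
        u <- sqrt(2) * tau * gh$nodes[k]
        p <- stats::plogis(eta0[sel] + u)
        exp(sum(stats::dbinom(y[sel], 1, p, log = TRUE)))
      }, numeric(1))
      ll <- ll + log(sum(gh$weights * li) / sqrt(pi))
    }
    -ll
  }
  start <- c(stats::coef(stats::glm.fit(X, y,
                                        family = stats::binomial())),
             log(0.5))
  opt <- stats::optim(start, neg_loglik, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(beta = opt$par[-length(opt$par)],
       tau = exp(opt$par[length(opt$par)]))
}

# Direct simulated LMM data (outside the race model) for estimator checks.
# center_participants = TRUE removes each participant's mean residual so the
# between-participant variance is exactly zero (REML boundary case).
make_lmm_data <- function(n_part, n_trials, beta_cond = 0.05,
                          beta_group = 0.1, beta_int = 0, subj_sd = 0.15,
                          sigma = 0.2, seed = 1,
                          center_participants = FALSE) {
  set.seed(seed)
  part <- sprintf("p%02d", seq_len(n_part))
  grp <- rep(c("young", "middle_aged"), length.out = n_part)
  b <- stats::rnorm(n_part, 0, subj_sd)
  df <- tidyr::expand_grid(participant_id = part,
                           trial = seq_len(n_trials))
  df$group <- grp[match(df$participant_id, part)]
  df$condition <- rep_len(c("congruent", "incongruent"), nrow(df))
  inc <- as.numeric(df$condition == "incongruent")
  mid <- as.numeric(df$group == "middle_aged")
  eps <- stats::rnorm(nrow(df), 0, sigma)
  if (center_participants) {
    eps <- eps - stats::ave(eps, df$participant_id)
  }
  df$log_rt <- 5.7 + beta_cond * inc + beta_group * mid +
    beta_int * inc * mid + b[match(df$participant_id, part)] + eps
  df
}

make_glmm_data <- function(n_part, n_trials, beta0 = 2.2, beta_cond = -1,
                           subj_sd = 0.5, seed = 1) {
  set.seed(seed)
  part <- sprintf("p%02d", seq_len(n_part))
  b <- stats::rnorm(n_part, 0, subj_sd)
  df <- tidyr::expand_grid(participant_id = part,
                           trial = seq_len(n_trials))
  df$group <- "young"
  df$condition <- rep_len(c("congruent", "incongruent"), nrow(df))
  inc <- as.numeric(df$condition == "incongruent")
  eta <- beta0 + beta_cond * inc + b[match(df$participant_id, part)]
  df$correct <- stats::rbinom(nrow(df), 1, stats::plogis(eta)) == 1
  df
}

# Treatment-coded factors matching the package's reference levels, for the
# plain lm/glm comparators.
prep_for_lm <- function(dat) {
  dat$condition <- stats::relevel(factor(dat$condition), "congruent")
  dat$group <- stats::relevel(factor(dat$group), "young")
  dat
}
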