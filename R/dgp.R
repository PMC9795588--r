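#' Configure one synthetic data-generating draw
#'
#' Describes a single draw from one of the two simulation scenarios. Both
#' scenarios share the covariate model `X ~ N(0, Sigma)` with a fresh random
#' sparse symmetric positive definite `Sigma` per dataset, and the exposure
#' model `logit E[T|X] = (1/sqrt(5)) sum_{j=1..5} beta_j X^(j)` with
#' `beta_j ~ U[-1, 1]`. Scenario 1 has a homogeneous treatment effect
#' `y = f(X, Omega) + theta T + eps`; scenario 2 adds treatment-covariate
#' interactions `y = (1-T) f(X, Omega0) + T f(X, Omega1) + theta T + eps`,
#' where `f(X, Omega) = (1/sqrt(10)) sum_{j=1..10} X^(Omega(j))` is a sparse
#' linear score over a random half of the covariates and `eps ~ N(0, 1)`.
#'
#' Under the alternative the effect size is drawn with variance
#' `theta_variance` (default 0.4, i.e. standard deviation `sqrt(0.4)`): in
#' scenario 1 `theta ~ N(0, 0.4)` directly, in scenario 2 the in-sample ATT
#' over the treated is the draw target. Under the null the effect is 0.
#'
#' @param scenario 1 (homogeneous effect) or 2 (heterogeneous effect).
#' @param n number of patients across both arms.
#' @param d number of covariates (default 20).
#' @param n_exposure_covariates covariates entering the exposure model
#'   (default 5; the first columns of `X`).
#' @param n_outcome_covariates covariates entering the outcome score
#'   (default 10; chosen by random permutation).
#' @param theta_variance variance of the effect-size prior (default 0.4).
#' @param null_hypothesis if `TRUE` the treatment effect is forced to 0.
#' @param cov_alpha sparsity of the covariance factor in `[0, 1]`
#'   (default 0.8; 1 gives a diagonal covariance).
#' @param seed RNG seed for the draw.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = 1, n = 500, d = 20,
                            n_exposure_covariates = 5,
                            n_outcome_covariates = 10,
                            theta_variance = 0.4,
                            null_hypothesis = FALSE,
                            cov_alpha = 0.8, seed = 1L) {
  stopifnot(scenario %in% c(1, 2), n >= 4, d >= 1,
            n_exposure_covariates <= d, n_outcome_covariates <= d,
            theta_variance > 0, cov_alpha >= 0, cov_alpha <= 1)
  structure(
    list(scenario = as.integer(scenario), n = as.integer(n),
         d = as.integer(d),
         n_exposure_covariates = as.integer(n_exposure_covariates),
         n_outcome_covariates = as.integer(n_outcome_covariates),
         theta_variance = theta_variance,
         null_hypothesis = isTRUE(null_hypothesis),
         cov_alpha = cov_alpha, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Draw a random sparse symmetric positive definite covariance matrix
#'
#' Builds `Sigma = A A'` from a random lower-triangular factor `A` with unit
#' diagonal whose off-diagonal entries are zero with probability `alpha` and
#' otherwise uniform on `[-0.9, -0.1] U [0.1, 0.9]`. The unit diagonal of
#' `A` guarantees positive definiteness for every draw; `alpha` controls the
#' expected fraction of structural zeros in the factor.
#'
#' @param d dimension.
#' @param alpha sparsity in `[0, 1]`; 1 yields a diagonal matrix.
#' @param seed optional RNG seed.
#' @return a `d x d` symmetric positive definite matrix.
#' @export
make_sparse_spd_covariance <- function(d, alpha = 0.8, seed = NULL) {
  stopifnot(d >= 1, alpha >= 0, alpha <= 1)
  local_seed_if(seed)
  A <- diag(1, d)
  if (d > 1) {
    low <- which(lower.tri(A))
    keep <- stats::runif(length(low)) >= alpha
    nk <- sum(keep)
    if (nk > 0) {
      mag <- stats::runif(nk, 0.1, 0.9)
      sgn <- sample(c(-1, 1), nk, replace = TRUE)
      A[low[keep]] <- sgn * mag
    }
  }
  sigma <- A %*% t(A)
  # unit-diagonal triangular factor => det(A) = 1, PD by construction
  stopifnot(all(is.finite(sigma)))
  sigma
}

#' Sample mean-zero Gaussian covariates
#'
#' @param n number of rows.
#' @param cov symmetric positive definite covariance matrix.
#' @param seed optional RNG seed.
#' @return an `n x d` matrix of i.i.d. `N(0, cov)` rows.
#' @export
sample_covariates <- function(n, cov, seed = NULL) {
  stopifnot(n >= 1)
  local_seed_if(seed)
  d <- nrow(cov)
  R <- chol(cov) # fails if not PD
  Z <- matrix(stats::rnorm(n * d), n, d)
  X <- Z %*% R
  colnames(X) <- paste0("x", seq_len(d))
  X
}

#' Sample treatment assignment from the logistic exposure model
#'
#' The propensity is `plogis((1/sqrt(k)) sum_{j=1..k} beta_j X^(j))` with
#' `k = length(beta)` applied to the first `k` covariate columns, and
#' treatment is Bernoulli at that propensity.
#'
#' @param X covariate matrix.
#' @param beta exposure coefficients (one per covariate used).
#' @param seed optional RNG seed.
#' @return list with `t` (binary assignment) and `propensity`.
#' @export
sample_treatment <- function(X, beta, seed = NULL) {
  k <- length(beta)
  stopifnot(k >= 1, ncol(X) >= k)
  local_seed_if(seed)
  eta <- drop(X[, seq_len(k), drop = FALSE] %*% beta) / sqrt(k)
  p <- stats::plogis(eta)
  list(t = stats::rbinom(nrow(X), 1L, p), propensity = p)
}

# Sparse linear outcome score f(X, Omega) = (1/sqrt(k)) sum_{j=1..k} X^(Omega(j))
outcome_score <- function(X, omega, k = 10L) {
  stopifnot(length(omega) >= k, ncol(X) >= k)
  rowSums(X[, omega[seq_len(k)], drop = FALSE]) / sqrt(k)
}

#' Generate scenario-1 outcomes (homogeneous treatment effect)
#'
#' `Y = f(X, Omega) + theta T + eps` with `eps ~ N(0, noise_sd^2)`. The
#' treatment effect is constant across units, so the true ATT equals
#' `theta`.
#'
#' @param X covariate matrix (`d >= n_outcome`).
#' @param t binary treatment vector.
#' @param omega permutation of the covariate indices; the first `n_outcome`
#'   entries carry unit coefficients, the rest are zeroed.
#' @param theta treatment effect.
#' @param n_outcome number of active outcome covariates (default 10).
#' @param noise_sd standard deviation of `eps` (default 1; 0 for noiseless
#'   checks).
#' @param seed optional RNG seed.
#' @return numeric outcome vector.
#' @export
sample_outcome_scenario1 <- function(X, t, omega, theta, n_outcome = 10L,
                                     noise_sd = 1, seed = NULL) {
  if (ncol(X) < n_outcome) stop("need at least ", n_outcome, " covariates")
  local_seed_if(seed)
  eps <- if (noise_sd > 0) stats::rnorm(nrow(X), 0, noise_sd) else 0
  outcome_score(X, omega, n_outcome) + theta * t + eps
}

#' Generate scenario-2 outcomes (heterogeneous treatment effect)
#'
#' `Y = (1-T) f(X, Omega0) + T f(X, Omega1) + theta T + eps`. The constant
#' `theta` is solved so that the realized in-sample ATT over the treated,
#' `mean_{T=1}[f(X, Omega1) - f(X, Omega0)] + theta`, equals `att_target`
#' exactly, anchoring bias metrics to a known reference.
#'
#' @param X covariate matrix.
#' @param t binary treatment vector with at least one treated unit.
#' @param omega0,omega1 permutations of the covariate indices for the
#'   control and treated outcome scores.
#' @param att_target the in-sample ATT the draw must realize.
#' @param n_outcome number of active outcome covariates (default 10).
#' @param noise_sd standard deviation of `eps` (default 1).
#' @param seed optional RNG seed.
#' @return list with `y`, `theta`, and the two potential-outcome score
#'   vectors `f0`, `f1`.
#' @export
sample_outcome_scenario2 <- function(X, t, omega0, omega1, att_target,
                                     n_outcome = 10L, noise_sd = 1,
                                     seed = NULL) {
  if (sum(t == 1L) < 1L) stop("scenario 2 needs at least one treated unit")
  local_seed_if(seed)
  f0 <- outcome_score(X, omega0, n_outcome)
  f1 <- outcome_score(X, omega1, n_outcome)
  theta <- att_target - mean(f1[t == 1L] - f0[t == 1L])
  eps <- if (noise_sd > 0) stats::rnorm(nrow(X), 0, noise_sd) else 0
  y <- (1 - t) * f0 + t * f1 + theta * t + eps
  list(y = y, theta = theta, f0 = f0, f1 = f1)
}

#' Generate one dataset and its ground truth from a scenario configuration
#'
#' Draws, in order: the covariance `Sigma` (fresh per dataset), covariates,
#' exposure coefficients `beta_j ~ U[-1, 1]`, treatment, the outcome
#' permutation(s), the effect size (`N(0, theta_variance)` under the
#' alternative, 0 under the null), and outcomes. If either arm ends up with
#' fewer than 2 units the whole draw is repeated with an incremented seed
#' (logged via `message`).
#'
#' @param config a [scenario_config()].
#' @return list with `dataset` (an [eca_dataset()]) and `truth` (list with
#'   `theta`, `att`, `beta`, `propensity`, `omega`/`omega0`/`omega1`,
#'   `sigma`, `seed_used`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- config$seed
  for (attempt in 1:100) {
    draw <- generate_dataset_once(config, seed)
    if (!is.null(draw)) return(draw)
    message("degenerate arm at seed ", seed, "; redrawing")
    seed <- seed + 1L
  }
  stop("could not draw a dataset with two populated arms")
}

generate_dataset_once <- function(config, seed) {
  local_seed_if(seed)
  d <- config$d
  sigma <- make_sparse_spd_covariance(d, config$cov_alpha)
  X <- sample_covariates(config$n, sigma)
  beta <- stats::runif(config$n_exposure_covariates, -1, 1)
  tr <- sample_treatment(X, beta)
  if (sum(tr$t == 1L) < 2L || sum(tr$t == 0L) < 2L) return(NULL)
  sd_theta <- sqrt(config$theta_variance)
  if (config$scenario == 1L) {
    omega <- sample.int(d)
    theta <- if (config$null_hypothesis) 0 else stats::rnorm(1, 0, sd_theta)
    y <- sample_outcome_scenario1(X, tr$t, omega, theta,
                                  config$n_outcome_covariates)
    truth <- list(theta = theta, att = theta, beta = beta,
                  propensity = tr$propensity, omega = omega,
                  sigma = sigma, seed_used = seed)
  } else {
    omega0 <- sample.int(d)
    omega1 <- sample.int(d)
    att_target <- if (config$null_hypothesis) 0 else stats::rnorm(1, 0, sd_theta)
    out <- sample_outcome_scenario2(X, tr$t, omega0, omega1, att_target,
                                    config$n_outcome_covariates)
    y <- out$y
    truth <- list(theta = out$theta, att = att_target, beta = beta,
                  propensity = tr$propensity, omega0 = omega0,
                  omega1 = omega1, sigma = sigma, seed_used = seed)
  }
  list(dataset = eca_dataset(X, tr$t, y), truth = truth)
}
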