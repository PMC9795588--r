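#' ATT point estimate with inference metadata
#'
#' Container for an estimated average treatment effect on the treated
#' together with its standard error, 95% confidence interval, two-sided
#' p-value, and method-specific diagnostics.
#'
#' @param method method name.
#' @param att point estimate.
#' @param se standard error (>= 0); `NA` when no inference was attached.
#' @param ci_low,ci_high confidence bounds.
#' @param p_value two-sided p-value in `[0, 1]`.
#' @param diagnostics named list of method-specific extras.
#' @return an object of class `att_estimate`.
#' @export
att_estimate <- function(method, att, se = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, p_value = NA_real_,
                         diagnostics = list()) {
  if (is.finite(se) && se < 0) stop("se must be non-negative")
  if (is.finite(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value must lie in [0, 1]")
  if (is.finite(ci_low) && is.finite(ci_high) &&
      !(ci_low <= att && att <= ci_high))
    stop("confidence interval must contain the point estimate")
  structure(
    list(method = method, att = att, se = se, ci_low = ci_low,
         ci_high = ci_high, p_value = p_value, diagnostics = diagnostics),
    class = "att_estimate"
  )
}

#' @export
print.att_estimate <- function(x, ...) {
  cat(sprintf("<att_estimate> %s: ATT = %.4f (se %.4f, 95%% CI [%.4f, %.4f], p = %.4g)\n",
              x$method, x$att, x$se, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Unadjusted difference in arm means
#'
#' `mean(Y | T = 1) - mean(Y | T = 0)`; measures the confounding bias one
#' incurs by ignoring covariates.
#'
#' @param dataset an [eca_dataset()].
#' @return scalar estimate.
#' @export
estimate_unadjusted <- function(dataset) {
  t <- dataset$t
  if (sum(t == 1L) < 1L || sum(t == 0L) < 1L) stop("both arms must be non-empty")
  mean(dataset$y[t == 1L]) - mean(dataset$y[t == 0L])
}

#' Inverse probability of treatment weighting estimator of the ATT
#'
#' `(1/n1) sum_i Y_i (T_i - e(X_i)(1 - T_i) / (1 - e(X_i)))`: treated units
#' enter with weight one, control units are reweighted by the propensity
#' odds to stand in for the treated population.
#'
#' @param dataset an [eca_dataset()].
#' @param e_hat propensity vector strictly inside `(0, 1)`.
#' @return scalar estimate.
#' @export
estimate_iptw <- function(dataset, e_hat) {
  t <- dataset$t
  n1 <- sum(t == 1L)
  if (n1 < 1L) stop("no treated units")
  if (any(e_hat <= 0) || any(e_hat >= 1))
    stop("propensities must lie strictly inside (0, 1)")
  sum(dataset$y * (t - e_hat * (1 - t) / (1 - e_hat))) / n1
}

#' Greedy nearest-neighbour propensity matching without replacement
#'
#' Repeatedly selects the globally closest remaining (treated, control)
#' pair by absolute propensity difference, stopping when a side is
#' exhausted or no remaining pair lies within the caliper. Ties are broken
#' by lowest treated index, then lowest control index. Matched distances
#' are non-decreasing in selection order.
#'
#' @param propensity_treated propensity scores of the treated units.
#' @param propensity_control propensity scores of the control units.
#' @param caliper maximum admissible propensity distance (default 0.25, on
#'   the raw propensity scale).
#' @return an object of class `match_result`: `pairs` (two-column matrix of
#'   treated/control indices in selection order), `distances`, `caliper`,
#'   and `discarded_treated`.
#' @export
match_greedy <- function(propensity_treated, propensity_control,
                         caliper = 0.25) {
  stopifnot(caliper > 0)
  n1 <- length(propensity_treated)
  n0 <- length(propensity_control)
  dist <- abs(outer(propensity_treated, propensity_control, "-"))
  cand <- which(dist <= caliper)
  empty <- function() structure(
    list(pairs = matrix(integer(0), 0, 2,
                        dimnames = list(NULL, c("treated", "control"))),
         distances = numeric(0), caliper = caliper,
         discarded_treated = seq_len(n1)),
    class = "match_result")
  if (length(cand) == 0L) return(empty())
  ti <- ((cand - 1L) %% n1) + 1L
  ci <- ((cand - 1L) %/% n1) + 1L
  ord <- order(dist[cand], ti, ci)
  ti <- ti[ord]; ci <- ci[ord]; dd <- dist[cand][ord]
  used_t <- logical(n1); used_c <- logical(n0)
  pt <- integer(0); pc <- integer(0); pd <- numeric(0)
  for (k in seq_along(ti)) {
    if (used_t[ti[k]] || used_c[ci[k]]) next
    used_t[ti[k]] <- TRUE; used_c[ci[k]] <- TRUE
    pt <- c(pt, ti[k]); pc <- c(pc, ci[k]); pd <- c(pd, dd[k])
    if (all(used_t) || all(used_c)) break
  }
  structure(
    list(pairs = cbind(treated = pt, control = pc), distances = pd,
         caliper = caliper, discarded_treated = which(!used_t)),
    class = "match_result"
  )
}

#' Propensity score matching estimator of the ATT
#'
#' Matches treated to control units with [match_greedy()] and averages the
#' within-pair outcome differences; unmatched patients are discarded from
#' the efficacy analysis.
#'
#' @param dataset an [eca_dataset()].
#' @param e_hat propensity vector for all units.
#' @param caliper maximum propensity distance (default 0.25).
#' @return list with `att` and `match` (the [match_greedy()] result, on
#'   within-arm indices).
#' @export
estimate_psm <- function(dataset, e_hat, caliper = 0.25) {
  t <- dataset$t
  idx1 <- which(t == 1L); idx0 <- which(t == 0L)
  m <- match_greedy(e_hat[idx1], e_hat[idx0], caliper)
  if (nrow(m$pairs) == 0L)
    stop("no matched pairs within the caliper (non-overlap)")
  y1 <- dataset$y[idx1[m$pairs[, "treated"]]]
  y0 <- dataset$y[idx0[m$pairs[, "control"]]]
  list(att = mean(y1 - y0), match = m)
}

#' G-computation estimator of the ATT
#'
#' Averages, over the experimental arm, the difference between the observed
#' outcome and the predicted counterfactual control outcome:
#' `(1/n1) sum_{T_i = 1} (Y_i - mu0(X_i))`.
#'
#' @param dataset an [eca_dataset()].
#' @param mu0_hat a fitted `eca_outcome_model`, or any function mapping a
#'   covariate matrix to predicted control outcomes.
#' @return scalar estimate.
#' @export
estimate_gcomp <- function(dataset, mu0_hat) {
  idx1 <- which(dataset$t == 1L)
  if (length(idx1) < 1L) stop("no treated units")
  X1 <- dataset$X[idx1, , drop = FALSE]
  mu <- if (is.function(mu0_hat)) mu0_hat(X1) else predict(mu0_hat, X1)
  mean(dataset$y[idx1] - mu)
}

# Doubly robust ATT score pieces on one auxiliary fold, given nuisance
# predictions from the complementary training folds. Returns the summed
# numerator sum_i [T_i r_i - odds_i (1 - T_i) r_i] with r_i = Y_i - mu0(X_i),
# the treated count, and the per-unit numerators (for the influence-function
# variance).
ddml_fold_score <- function(y, t, mu0_pred, e_pred) {
  r <- y - mu0_pred
  odds <- e_pred / (1 - e_pred)
  psi <- t * r - odds * (1 - t) * r
  list(psi = psi, sum_psi = sum(psi), n1 = sum(t == 1L))
}

#' Doubly debiased machine learning estimator of the ATT
#'
#' Cross-fitted doubly robust estimator: for each random partition of the
#' data into `n_folds` folds, each fold serves in turn as the auxiliary
#' set while the exposure and control-outcome models are fitted on the
#' complement (their penalties tuned by internal cross-validation, i.e.
#' nested within the sample split). On the auxiliary fold the
#' G-computation estimate is corrected by the propensity-odds-weighted mean
#' of the control residuals,
#' `ATT_GC(aux) - (1/n1_aux) sum_{i in aux} odds_i (1 - T_i)(Y_i - mu0(X_i))`.
#' Fold scores are pooled within a split (treated-count weighting) and the
#' estimate is averaged over `n_splits` independent partitions. The
#' variance combines the within-split influence-function variance with the
#' cross-split dispersion:
#' `var = mean_s [ var_s + (theta_s - theta_bar)^2 ]`.
#'
#' @param dataset an [eca_dataset()].
#' @param n_folds folds per partition (default 2: a training and an
#'   auxiliary half, both used by cross-fitting).
#' @param n_splits number of random partitions averaged (default 20).
#' @param n_cv_folds folds of the nested penalty cross-validation.
#' @param penalty_grid candidate penalty strengths for both nuisances.
#' @param seed optional RNG seed.
#' @return an [att_estimate()] with per-split estimates and variances in
#'   `diagnostics`.
#' @export
estimate_ddml <- function(dataset, n_folds = 2L, n_splits = 20L,
                          n_cv_folds = 5L,
                          penalty_grid = default_penalty_grid(),
                          seed = NULL) {
  stopifnot(n_folds >= 2L, n_splits >= 1L)
  local_seed_if(seed)
  t <- dataset$t; y <- dataset$y; X <- dataset$X
  n <- length(t)
  p1 <- mean(t == 1L)
  split_est <- numeric(n_splits)
  split_var <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    foldid <- ddml_partition(t, n_folds)
    psi_all <- numeric(n)
    n1_total <- 0L
    for (k in seq_len(n_folds)) {
      aux <- which(foldid == k)
      train <- which(foldid != k)
      emod <- fit_exposure_model(X[train, , drop = FALSE], t[train],
                                 n_cv_folds, penalty_grid)
      omod <- fit_outcome_model(X[train, , drop = FALSE], t[train], y[train],
                                n_cv_folds, penalty_grid)
      sc <- ddml_fold_score(y[aux], t[aux],
                            predict(omod, X[aux, , drop = FALSE]),
                            predict(emod, X[aux, , drop = FALSE]))
      psi_all[aux] <- sc$psi
      n1_total <- n1_total + sc$n1
    }
    est <- sum(psi_all) / n1_total
    # influence function of the pooled ATT score; n * var(phi)/n estimates
    # the sampling variance of the split estimate
    phi <- (psi_all - t * est) / p1
    split_est[s] <- est
    split_var[s] <- sum(phi^2) / n^2
  }
  res <- summarize_ddml_inference(split_est, split_var)
  att_estimate("ddml", res$att, res$se, res$ci_low, res$ci_high,
               res$p_value,
               diagnostics = list(split_estimates = split_est,
                                  split_variances = split_var,
                                  n_folds = n_folds, n_splits = n_splits))
}

# Stratified fold assignment keeping both arms in every fold; re-randomizes
# (up to 10 attempts, logged) if a fold ends up single-class.
ddml_partition <- function(t, n_folds) {
  for (attempt in 1:10) {
    foldid <- balanced_folds(t, n_folds)
    ok <- all(vapply(seq_len(n_folds), function(k) {
      tk <- t[foldid == k]
      sum(tk == 1L) >= 1L && sum(tk == 0L) >= 1L
    }, logical(1)))
    if (ok) return(foldid)
    message("single-class fold; re-randomizing the split")
  }
  stop("could not build folds containing both arms after 10 attempts")
}

#' Estimate the ATT by a named method, with inference
#'
#' Uniform front door over the five estimators. `unadjusted`, `psm`,
#' `iptw` and `gcomp` fit their nuisance models internally and attach
#' nonparametric bootstrap inference ([bootstrap_estimate()]); `ddml` uses
#' its sample-splitting variance.
#'
#' @param dataset an [eca_dataset()].
#' @param method one of `"unadjusted"`, `"psm"`, `"iptw"`, `"gcomp"`,
#'   `"ddml"`.
#' @param bootstrap_b bootstrap replicates (default 300).
#' @param caliper PSM caliper.
#' @param n_folds,n_splits DDML partition settings.
#' @param n_cv_folds penalty cross-validation folds.
#' @param penalty_grid candidate penalty strengths.
#' @param seed optional RNG seed.
#' @return an [att_estimate()].
#' @export
estimate_att <- function(dataset,
                         method = c("unadjusted", "psm", "iptw", "gcomp", "ddml"),
                         bootstrap_b = 300L, caliper = 0.25,
                         n_folds = 2L, n_splits = 20L, n_cv_folds = 5L,
                         penalty_grid = default_penalty_grid(),
                         seed = NULL) {
  method <- match.arg(method)
  if (method == "ddml") {
    estimate_ddml(dataset, n_folds, n_splits, n_cv_folds, penalty_grid, seed)
  } else {
    bootstrap_estimate(dataset, method, B = bootstrap_b, caliper = caliper,
                       n_cv_folds = n_cv_folds, penalty_grid = penalty_grid,
                       seed = seed)
  }
}
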