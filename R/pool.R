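#' Generate a synthetic pool of randomized trials
#'
#' Emulates the structure of an internal replication study: `n_trials`
#' two-or-more-arm randomized trials share one outcome model (a sparse
#' linear score over the covariates plus one additive effect per treatment
#' label) and one covariance `Sigma`, but differ in their covariate means.
#' Trial `k` draws every patient's covariates from `N(m_k, Sigma)` with a
#' trial-specific shift `m_k` of norm `shift_scale`, so that within-trial
#' comparisons are randomized while cross-trial comparisons (replacing one
#' trial's control arm by another trial's arm) are confounded by the
#' covariate shift.
#'
#' Arm labels are `"control"`, `"trt_a"`, `"trt_b"`, ... and every trial
#' carries every label. Non-control labels receive additive effects drawn
#' from `N(0, theta_variance)`, shared across trials.
#'
#' @param n_trials number of trials (>= 2).
#' @param arms_per_trial arms per trial, including the control arm.
#' @param n_per_arm patients per arm.
#' @param shift_scale Euclidean norm of each trial's covariate mean shift;
#'   0 removes cross-trial confounding.
#' @param config_base a [scenario_config()] supplying `d`, `cov_alpha`,
#'   `n_outcome_covariates` and `theta_variance` (its scenario/n/seed
#'   fields are ignored).
#' @param seed RNG seed.
#' @return an object of class `trial_pool`.
#' @export
generate_trial_pool <- function(n_trials = 5L, arms_per_trial = 2L,
                                n_per_arm = 150L, shift_scale = 1,
                                config_base = scenario_config(),
                                seed = 1L) {
  stopifnot(n_trials >= 2L, arms_per_trial >= 2L, n_per_arm >= 2L,
            shift_scale >= 0)
  local_seed_if(seed)
  d <- config_base$d
  k_out <- config_base$n_outcome_covariates
  labels <- c("control",
              paste0("trt_", letters[seq_len(arms_per_trial - 1L)]))
  sigma <- make_sparse_spd_covariance(d, config_base$cov_alpha)
  omega <- sample.int(d)
  theta <- c(0, stats::rnorm(arms_per_trial - 1L, 0,
                             sqrt(config_base$theta_variance)))
  names(theta) <- labels
  trials <- vector("list", n_trials)
  shifts <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    z <- stats::rnorm(d)
    m_k <- if (shift_scale > 0) shift_scale * z / sqrt(sum(z^2)) else
      rep(0, d)
    shifts[[k]] <- m_k
    arms <- lapply(labels, function(lab) {
      X <- sweep(sample_covariates(n_per_arm, sigma), 2L, m_k, "+")
      y <- outcome_score(X, omega, k_out) + theta[[lab]] +
        stats::rnorm(n_per_arm)
      list(X = X, y = y)
    })
    names(arms) <- labels
    trials[[k]] <- list(id = paste0("trial_", k), arms = arms)
  }
  structure(
    list(trials = trials, treatment_labels = labels, omega = omega,
         theta = theta, sigma = sigma, shift_magnitudes = shifts,
         d = d, n_per_arm = as.integer(n_per_arm),
         n_outcome_covariates = k_out, shift_scale = shift_scale,
         seed = as.integer(seed)),
    class = "trial_pool"
  )
}

#' @export
print.trial_pool <- function(x, ...) {
  cat(sprintf(
    "<trial_pool> %d trials x %d arms (%s), %d patients/arm, d = %d, shift %.2f\n",
    length(x$trials), length(x$treatment_labels),
    paste(x$treatment_labels, collapse = ", "),
    x$n_per_arm, x$d, x$shift_scale))
  invisible(x)
}

#' Enumerate artificial non-randomized comparisons from a trial pool
#'
#' In `negative_control` mode, pairs arms carrying the *same* treatment
#' label across distinct trials (ordered pairs), so the true ATT is zero.
#' In `rct_replication` mode, pairs each trial's treatment arm with another
#' trial's control arm, and attaches the within-trial randomized comparison
#' (Welch two-sample estimate, 95% confidence interval and p-value) as the
#' reference.
#'
#' @param pool a [generate_trial_pool()] result.
#' @param mode `"negative_control"` or `"rct_replication"`.
#' @return list of comparisons; each has `dataset` (an [eca_dataset()]
#'   with the experimental arm coded `t = 1`), `label`,
#'   `experimental_trial`, `control_trial`, `true_att`, and in RCT mode an
#'   `rct` reference list.
#' @export
build_comparisons <- function(pool,
                              mode = c("negative_control", "rct_replication")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pool, "trial_pool"))
  K <- length(pool$trials)
  out <- list()
  as_dataset <- function(arm1, arm0) {
    eca_dataset(rbind(arm1$X, arm0$X),
                c(rep(1L, nrow(arm1$X)), rep(0L, nrow(arm0$X))),
                c(arm1$y, arm0$y))
  }
  if (mode == "negative_control") {
    for (lab in pool$treatment_labels)
      for (i in seq_len(K)) for (j in seq_len(K)) {
        if (i == j) next
        out[[length(out) + 1L]] <- list(
          dataset = as_dataset(pool$trials[[i]]$arms[[lab]],
                               pool$trials[[j]]$arms[[lab]]),
          label = lab, experimental_trial = i, control_trial = j,
          true_att = 0)
      }
    return(out)
  }
  trt_labels <- setdiff(pool$treatment_labels, "control")
  for (lab in trt_labels)
    for (i in seq_len(K)) {
      arm1 <- pool$trials[[i]]$arms[[lab]]
      ctrl_i <- pool$trials[[i]]$arms[["control"]]
      tt <- stats::t.test(arm1$y, ctrl_i$y)
      rct <- list(att = unname(tt$estimate[1] - tt$estimate[2]),
                  ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                  p_value = tt$p.value)
      for (j in seq_len(K)) {
        if (i == j) next
        out[[length(out) + 1L]] <- list(
          dataset = as_dataset(arm1, pool$trials[[j]]$arms[["control"]]),
          label = lab, experimental_trial = i, control_trial = j,
          true_att = pool$theta[[lab]], rct = rct)
      }
    }
  out
}

#' Serialize a trial pool to a directory of CSVs plus a JSON manifest
#'
#' Each arm becomes one CSV (`trial_<k>_<label>.csv`, columns
#' `y,x1,...,xd`); `manifest.json` records trial ids, arm labels and
#' files, shift vectors, the outcome-model parameters and the seed.
#'
#' @param pool a [generate_trial_pool()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_pool <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    treatment_labels = pool$treatment_labels, d = pool$d,
    n_per_arm = pool$n_per_arm,
    n_outcome_covariates = pool$n_outcome_covariates,
    shift_scale = pool$shift_scale, seed = pool$seed,
    omega = pool$omega, theta = as.list(pool$theta),
    trials = lapply(seq_along(pool$trials), function(k) list(
      id = pool$trials[[k]]$id,
      shift = pool$shift_magnitudes[[k]],
      arms = lapply(pool$treatment_labels, function(lab) list(
        label = lab,
        file = sprintf("trial_%d_%s.csv", k, lab)))))
  )
  for (k in seq_along(pool$trials))
    for (lab in pool$treatment_labels) {
      arm <- pool$trials[[k]]$arms[[lab]]
      df <- data.frame(y = arm$y, arm$X, check.names = FALSE)
      utils::write.csv(df, file.path(dir, sprintf("trial_%d_%s.csv", k, lab)),
                       row.names = FALSE, quote = FALSE)
    }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a trial pool written by [write_trial_pool()]
#'
#' @param dir directory containing `manifest.json` and the arm CSVs.
#' @return a `trial_pool` object.
#' @export
read_trial_pool <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyDataFrame = FALSE)
  labels <- unlist(manifest$treatment_labels)
  trials <- lapply(manifest$trials, function(tr) {
    arms <- lapply(tr$arms, function(a) {
      df <- utils::read.csv(file.path(dir, a$file), check.names = FALSE)
      list(X = as.matrix(df[, setdiff(names(df), "y"), drop = FALSE]),
           y = df$y)
    })
    names(arms) <- vapply(tr$arms, function(a) a$label, character(1))
    list(id = tr$id, arms = arms)
  })
  theta <- unlist(manifest$theta)
  structure(
    list(trials = trials, treatment_labels = labels,
         omega = as.integer(unlist(manifest$omega)), theta = theta,
         sigma = NULL,
         shift_magnitudes = lapply(manifest$trials,
                                   function(tr) as.numeric(unlist(tr$shift))),
         d = manifest$d, n_per_arm = manifest$n_per_arm,
         n_outcome_covariates = manifest$n_outcome_covariates,
         shift_scale = manifest$shift_scale, seed = manifest$seed),
    class = "trial_pool"
  )
}
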