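#' Summarize Monte Carlo replicates of one estimator
#'
#' Computes the evaluation metrics over a set of simulation replicates:
#' bias `mean(est - truth)`, MAE, MSE, the matched-Gaussian confidence
#' interval log-width ([ci_log_width()]), the rejection rate at `alpha`
#' (reported as type I error when every truth is 0, as power otherwise),
#' and the coverage of the truth by the confidence intervals.
#'
#' @param estimates list of [att_estimate()] objects (one per replicate).
#' @param truths numeric vector of true ATT values, one per replicate.
#' @param alpha significance cutoff (default 0.05).
#' @return a one-row `data.frame` with columns `method`, `n_replicates`,
#'   `bias`, `mae`, `mse`, `ci_log_width`, `rejection_rate`,
#'   `rate_type` (`"type_I_error"` or `"power"`), `coverage`.
#' @export
summarize_replicates <- function(estimates, truths, alpha = 0.05) {
  if (length(estimates) == 0L) stop("no replicates to summarize")
  if (length(estimates) != length(truths))
    stop("estimates and truths must have equal length")
  est <- vapply(estimates, function(e) e$att, numeric(1))
  p <- vapply(estimates, function(e) e$p_value, numeric(1))
  lo <- vapply(estimates, function(e) e$ci_low, numeric(1))
  hi <- vapply(estimates, function(e) e$ci_high, numeric(1))
  err <- est - truths
  widths <- hi - lo
  data.frame(
    method = estimates[[1L]]$method,
    n_replicates = length(estimates),
    bias = mean(err),
    mae = mean(abs(err)),
    mse = mean(err^2),
    ci_log_width = if (all(is.finite(widths)) && all(widths > 0))
      ci_log_width(widths) else NA_real_,
    rejection_rate = mean(p < alpha),
    rate_type = if (all(truths == 0)) "type_I_error" else "power",
    coverage = mean(lo <= truths & truths <= hi),
    stringsAsFactors = FALSE
  )
}

#' Matched-Gaussian log-width of confidence intervals
#'
#' Summarizes a set of 95% confidence interval widths by the log-variance
#' of the Gaussian distribution whose central 95% interval would have the
#' average observed width: `sd = mean(width) / (2 * z_0.975)` and the
#' statistic is `log(sd^2)` (natural log).
#'
#' @param ci_widths positive interval widths across replicates.
#' @return scalar log-variance.
#' @export
ci_log_width <- function(ci_widths) {
  if (any(!is.finite(ci_widths)) || any(ci_widths <= 0))
    stop("interval widths must be positive and finite")
  z <- 1.959964
  sd_matched <- mean(ci_widths) / (2 * z)
  log(sd_matched^2)
}

#' Replication metrics for one method over a set of artificial comparisons
#'
#' In `negative_control` mode the ground truth is a zero effect: reports
#' MAE and MSE against 0, the mean confidence interval width, and the
#' coverage of 0. In `rct_replication` mode the within-trial randomized
#' estimate is the reference: reports pseudo-bias (mean of ECA estimate
#' minus RCT estimate), pseudo-MSE, the mean ECA confidence interval
#' width, estimate agreement (fraction of ECA estimates inside the RCT 95%
#' confidence interval) and regulatory agreement (fraction of comparisons
#' where both analyses fall on the same side of `p = 0.05`). Agreement
#' fractions keep their numerator and denominator.
#'
#' @param eca_estimates list of [att_estimate()] objects from the
#'   non-randomized comparisons.
#' @param rct_references in RCT mode, a list of lists with `att`,
#'   `ci_low`, `ci_high`, `p_value` from the randomized reference; ignored
#'   in negative-control mode.
#' @param mode `"negative_control"` or `"rct_replication"`.
#' @param alpha significance cutoff for regulatory agreement.
#' @return a one-row `data.frame` of replication metrics.
#' @export
replication_metrics <- function(eca_estimates, rct_references = NULL,
                                mode = c("negative_control", "rct_replication"),
                                alpha = 0.05) {
  mode <- match.arg(mode)
  n <- length(eca_estimates)
  if (n == 0L) stop("no comparisons supplied")
  est <- vapply(eca_estimates, function(e) e$att, numeric(1))
  p <- vapply(eca_estimates, function(e) e$p_value, numeric(1))
  lo <- vapply(eca_estimates, function(e) e$ci_low, numeric(1))
  hi <- vapply(eca_estimates, function(e) e$ci_high, numeric(1))
  width <- mean(hi - lo)
  method <- eca_estimates[[1L]]$method
  if (mode == "negative_control") {
    cov_n <- sum(lo <= 0 & 0 <= hi)
    return(data.frame(
      method = method, mode = mode, n_comparisons = n,
      pseudo_bias = mean(est), mae = mean(abs(est)), mse = mean(est^2),
      mean_ci_width = width,
      coverage = cov_n / n, coverage_hits = cov_n,
      estimate_agreement = NA_real_, estimate_agreement_hits = NA_integer_,
      regulatory_agreement = NA_real_, regulatory_agreement_hits = NA_integer_,
      stringsAsFactors = FALSE
    ))
  }
  if (is.null(rct_references) || length(rct_references) != n)
    stop("rct_replication mode needs one RCT reference per comparison")
  rct_est <- vapply(rct_references, function(r) r$att, numeric(1))
  rct_lo <- vapply(rct_references, function(r) r$ci_low, numeric(1))
  rct_hi <- vapply(rct_references, function(r) r$ci_high, numeric(1))
  rct_p <- vapply(rct_references, function(r) r$p_value, numeric(1))
  ea_n <- sum(rct_lo <= est & est <= rct_hi)
  ra_n <- sum((p < alpha) == (rct_p < alpha))
  cov_n <- sum(lo <= rct_est & rct_est <= hi)
  data.frame(
    method = method, mode = mode, n_comparisons = n,
    pseudo_bias = mean(est - rct_est),
    mae = mean(abs(est - rct_est)), mse = mean((est - rct_est)^2),
    mean_ci_width = width,
    coverage = cov_n / n, coverage_hits = cov_n,
    estimate_agreement = ea_n / n, estimate_agreement_hits = ea_n,
    regulatory_agreement = ra_n / n, regulatory_agreement_hits = ra_n,
    stringsAsFactors = FALSE
  )
}
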