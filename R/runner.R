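#' Configure a Monte Carlo simulation study
#'
#' Cross of scenario x sample size x hypothesis, each cell evaluated with
#' `n_replicates` simulated datasets. Every per-replicate seed is a
#' deterministic function of the master seed, the condition index and the
#' replicate index ([derive_seed()]), so studies are reproducible
#' end-to-end.
#'
#' @param scenarios scenario ids (subset of `c(1, 2)`).
#' @param ns total sample sizes (default `c(250, 500, 1000)`).
#' @param hypotheses `"null"`, `"alternative"`, or both.
#' @param methods estimators to run.
#' @param n_replicates Monte Carlo replicates per condition (default 300).
#' @param bootstrap_b bootstrap replicates (default 300).
#' @param ddml_folds,ddml_splits DDML cross-fitting settings.
#' @param d covariate count.
#' @param alpha significance cutoff.
#' @param master_seed master seed.
#' @param out_dir optional directory for result CSVs.
#' @return an object of class `study_config`.
#' @export
study_config <- function(scenarios = 1L, ns = c(250L, 500L, 1000L),
                         hypotheses = c("null", "alternative"),
                         methods = c("unadjusted", "psm", "iptw",
                                     "gcomp", "ddml"),
                         n_replicates = 300L, bootstrap_b = 300L,
                         ddml_folds = 2L, ddml_splits = 20L, d = 20L,
                         alpha = 0.05, master_seed = 1L, out_dir = NULL) {
  stopifnot(all(scenarios %in% c(1L, 2L)),
            all(hypotheses %in% c("null", "alternative")),
            all(methods %in% c("unadjusted", "psm", "iptw", "gcomp", "ddml")))
  structure(
    list(scenarios = as.integer(scenarios), ns = as.integer(ns),
         hypotheses = hypotheses, methods = methods,
         n_replicates = as.integer(n_replicates),
         bootstrap_b = as.integer(bootstrap_b),
         ddml_folds = as.integer(ddml_folds),
         ddml_splits = as.integer(ddml_splits), d = as.integer(d),
         alpha = alpha, master_seed = as.integer(master_seed),
         out_dir = out_dir),
    class = "study_config"
  )
}

#' Run a Monte Carlo simulation study
#'
#' For every condition in the configuration, generates `n_replicates`
#' datasets, runs each requested estimator with its inference (shared
#' bootstrap resamples for the estimators that bootstrap; sample-splitting
#' for DDML), and summarizes the replicates with
#' [summarize_replicates()]. Estimator failures on a replicate are
#' recorded and skipped. If `out_dir` is set, writes
#' `simulation_summary.csv`, `replicate_estimates.csv` and a JSON run
#' manifest.
#'
#' @param config a [study_config()].
#' @param verbose print a progress line per condition.
#' @return list with `summary` (one row per method x condition),
#'   `replicates` (per-replicate estimates for audit), and `config`.
#' @export
run_simulation_study <- function(config, verbose = interactive()) {
  stopifnot(inherits(config, "study_config"))
  grid <- expand.grid(scenario = config$scenarios, n = config$ns,
                      hypothesis = config$hypotheses,
                      stringsAsFactors = FALSE)
  boot_methods <- intersect(config$methods,
                            c("unadjusted", "psm", "iptw", "gcomp"))
  run_ddml <- "ddml" %in% config$methods
  summaries <- list()
  rep_rows <- list()
  for (g in seq_len(nrow(grid))) {
    scen <- grid$scenario[g]; n <- grid$n[g]; hyp <- grid$hypothesis[g]
    ests <- stats::setNames(
      lapply(config$methods, function(m) vector("list", config$n_replicates)),
      config$methods)
    truths <- numeric(config$n_replicates)
    n_failures <- stats::setNames(integer(length(config$methods)),
                                  config$methods)
    for (r in seq_len(config$n_replicates)) {
      sc <- scenario_config(scenario = scen, n = n, d = config$d,
                            null_hypothesis = (hyp == "null"),
                            seed = derive_seed(config$master_seed, g, r, 1L))
      gen <- generate_dataset(sc)
      truths[r] <- gen$truth$att
      if (length(boot_methods) > 0L) {
        res <- tryCatch(
          bootstrap_atts(gen$dataset, boot_methods, B = config$bootstrap_b,
                         seed = derive_seed(config$master_seed, g, r, 2L)),
          error = function(e) NULL)
        if (is.null(res)) {
          n_failures[boot_methods] <- n_failures[boot_methods] + 1L
        } else for (m in boot_methods) ests[[m]][[r]] <- res[[m]]
      }
      if (run_ddml) {
        dd <- tryCatch(
          estimate_ddml(gen$dataset, n_folds = config$ddml_folds,
                        n_splits = config$ddml_splits,
                        seed = derive_seed(config$master_seed, g, r, 3L)),
          error = function(e) NULL)
        if (is.null(dd)) n_failures[["ddml"]] <- n_failures[["ddml"]] + 1L
        else ests[["ddml"]][[r]] <- dd
      }
    }
    for (m in config$methods) {
      keep <- !vapply(ests[[m]], is.null, logical(1))
      if (!any(keep)) next
      s <- summarize_replicates(ests[[m]][keep], truths[keep], config$alpha)
      s$scenario <- scen; s$n <- n; s$hypothesis <- hyp
      s$n_failed <- n_failures[[m]]
      summaries[[length(summaries) + 1L]] <- s
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        scenario = scen, n = n, hypothesis = hyp, method = m,
        replicate = which(keep), truth = truths[keep],
        att = vapply(ests[[m]][keep], function(e) e$att, numeric(1)),
        se = vapply(ests[[m]][keep], function(e) e$se, numeric(1)),
        ci_low = vapply(ests[[m]][keep], function(e) e$ci_low, numeric(1)),
        ci_high = vapply(ests[[m]][keep], function(e) e$ci_high, numeric(1)),
        p_value = vapply(ests[[m]][keep], function(e) e$p_value, numeric(1)),
        stringsAsFactors = FALSE)
    }
    if (verbose)
      message(sprintf("condition %d/%d done (scenario %d, n %d, %s)",
                      g, nrow(grid), scen, n, hyp))
  }
  out <- list(summary = do.call(rbind, summaries),
              replicates = do.call(rbind, rep_rows), config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$summary,
                     file.path(config$out_dir, "simulation_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(out$replicates,
                     file.path(config$out_dir, "replicate_estimates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      unclass(config), file.path(config$out_dir, "run_manifest.json"),
      digits = NA, auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  out
}

#' Run a replication study over a trial pool
#'
#' Enumerates all valid artificial comparisons in the requested mode
#' ([build_comparisons()]), applies each estimator with its inference, and
#' aggregates per-method metrics with [replication_metrics()].
#'
#' @param pool a [generate_trial_pool()] result.
#' @param mode `"negative_control"` or `"rct_replication"`.
#' @param methods estimators to run.
#' @param bootstrap_b bootstrap replicates.
#' @param ddml_folds,ddml_splits DDML settings.
#' @param alpha significance cutoff.
#' @param seed master seed for the inference streams.
#' @return list with `report` (one row per method), `per_comparison`
#'   (long table of estimates), and `comparisons`.
#' @export
run_replication_study <- function(pool,
                                  mode = c("negative_control",
                                           "rct_replication"),
                                  methods = c("unadjusted", "psm", "iptw",
                                              "gcomp", "ddml"),
                                  bootstrap_b = 300L, ddml_folds = 2L,
                                  ddml_splits = 20L, alpha = 0.05,
                                  seed = 1L) {
  mode <- match.arg(mode)
  comparisons <- build_comparisons(pool, mode)
  if (length(comparisons) == 0L) stop("pool supports no comparison in this mode")
  boot_methods <- intersect(methods, c("unadjusted", "psm", "iptw", "gcomp"))
  run_ddml <- "ddml" %in% methods
  per_method <- stats::setNames(
    lapply(methods, function(m) vector("list", length(comparisons))), methods)
  for (i in seq_along(comparisons)) {
    d <- comparisons[[i]]$dataset
    if (length(boot_methods) > 0L) {
      res <- bootstrap_atts(d, boot_methods, B = bootstrap_b,
                            seed = derive_seed(seed, i, 1L))
      for (m in boot_methods) per_method[[m]][[i]] <- res[[m]]
    }
    if (run_ddml)
      per_method[["ddml"]][[i]] <- estimate_ddml(
        d, n_folds = ddml_folds, n_splits = ddml_splits,
        seed = derive_seed(seed, i, 2L))
  }
  rct_refs <- if (mode == "rct_replication")
    lapply(comparisons, function(cc) cc$rct)
  report <- do.call(rbind, lapply(methods, function(m)
    replication_metrics(per_method[[m]], rct_refs, mode, alpha)))
  per_comparison <- do.call(rbind, lapply(methods, function(m) {
    data.frame(
      method = m,
      comparison = seq_along(comparisons),
      label = vapply(comparisons, function(cc) cc$label, character(1)),
      experimental_trial = vapply(comparisons,
                                  function(cc) cc$experimental_trial,
                                  numeric(1)),
      control_trial = vapply(comparisons, function(cc) cc$control_trial,
                             numeric(1)),
      att = vapply(per_method[[m]], function(e) e$att, numeric(1)),
      p_value = vapply(per_method[[m]], function(e) e$p_value, numeric(1)),
      stringsAsFactors = FALSE)
  }))
  list(report = report, per_comparison = per_comparison,
       comparisons = comparisons)
}
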