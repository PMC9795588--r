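#!/usr/bin/env Rscript
# Stage 2: estimation error, power and confidence interval width under the
# scenario-1 alternative (theta ~ N(0, 0.4)) at n = 1000, plus the
# heterogeneous-effect scenario 2 for comparison.
#
# Expectation from the design: outcome-modelling estimators (G-computation,
# DDML) achieve smaller bias than the propensity-score pair, DDML has the
# smallest bias by construction, and G-computation the narrowest intervals.
# Writes results/sim_power.csv.

library(ecabench)

dir.create("results", showWarnings = FALSE)
cfg <- study_config(
  scenarios = c(1, 2), ns = 1000, hypotheses = "alternative",
  methods = c("unadjusted", "psm", "iptw", "gcomp", "ddml"),
  n_replicates = 50, bootstrap_b = 100, ddml_splits = 5,
  master_seed = 20260102, out_dir = "results/sim_power")
res <- run_simulation_study(cfg, verbose = TRUE)

tab <- res$summary[, c("scenario", "method", "bias", "mae", "mse",
                       "ci_log_width", "rejection_rate")]
names(tab)[names(tab) == "rejection_rate"] <- "power"
print(tab, row.names = FALSE, digits = 3)
utils::write.csv(tab, "results/sim_power.csv", row.names = FALSE)

s1 <- tab[tab$scenario == 1, ]
cat(sprintf("\nScenario 1, n=1000: |bias| DDML %.3f vs G-computation %.3f; ",
            abs(s1$bias[s1$method == "ddml"]),
            abs(s1$bias[s1$method == "gcomp"])))
adj <- s1[s1$method != "unadjusted", ]
cat(sprintf("narrowest CI: %s.\n",
            adj$method[which.min(adj$ci_log_width)]))
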