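Package: ecabench
Title: Benchmarking ATT Estimators for External Control Arm Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and replication benchmarks for estimators of the
    average treatment effect on the treated (ATT) in external control arm
    analyses. Implements the unadjusted difference in means, greedy caliper
    propensity score matching, inverse probability of treatment weighting,
    G-computation, and doubly debiased machine learning with cross-fitting,
    together with ridge/lasso nuisance models, nonparametric bootstrap and
    sample-splitting inference, two synthetic data-generating scenarios with
    confounding, a synthetic multi-trial pool emulating internal replication
    designs, and Monte Carlo evaluation metrics (bias, MAE, MSE, matched
    Gaussian confidence interval log-width, type I error, power, coverage,
    and replication agreement statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
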