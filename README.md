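# ecabench

Benchmarking estimators of the **average treatment effect on the treated
(ATT)** for external control arm (ECA) analyses — the setting where a
single-arm trial's experimental cohort is compared against control
patients assembled from external data, so that baseline differences
between the two cohorts confound a naive comparison.

The package is aimed at biostatisticians evaluating which adjustment
method to trust for a given ECA sample size. It implements, with full
inference, the five standard candidates:

| method | estimator |
|---|---|
| unadjusted | difference in arm means (bias yardstick) |
| PSM | greedy caliper propensity-score matching without replacement |
| IPTW | odds-weighting: ATT = (1/n₁) Σᵢ Yᵢ (Tᵢ − ê(Xᵢ)(1−Tᵢ)/(1−ê(Xᵢ))) |
| G-computation | (1/n₁) Σ_{Tᵢ=1} (Yᵢ − μ̂₀(Xᵢ)) with a lasso control-outcome model |
| DDML | cross-fitted doubly robust score; G-computation minus an estimate of its regularization bias, averaged over repeated sample splits |

Nuisance models are ridge logistic (exposure, ê) and lasso linear on
controls (outcome, μ̂₀), penalties tuned by 5-fold cross-validation.
Inference is by nonparametric bootstrap (pipeline refits included) for
the first four methods and by a dispersion-inflated sample-splitting
variance for DDML.

Around the estimators sit the benchmarking instruments: two synthetic
data-generating scenarios (homogeneous and heterogeneous treatment
effects over 20 Gaussian covariates with a random sparse covariance and
logistic confounding), a synthetic multi-trial pool that emulates
internal replication designs (negative-control and RCT-replication
comparisons), Monte Carlo metrics (bias, MAE, MSE, matched-Gaussian CI
log-width, type I error, power, coverage) and replication metrics
(pseudo-bias, pseudo-MSE, estimate and regulatory agreement). The
vignette `vignettes/eca-att-methods.Rmd` documents the models, defaults
and design choices.

## Worked example

```r
library(ecabench)

# one confounded dataset: scenario 1, 500 patients, true ATT = theta
gen <- generate_dataset(scenario_config(scenario = 1, n = 500, seed = 33))
gen$truth$att
#> [1] 0.2593327

estimate_att(gen$dataset, "unadjusted", bootstrap_b = 100, seed = 1)
#> <att_estimate> unadjusted: ATT = 0.4242 (se 0.1314, 95% CI [0.1968, 0.7009], p = 0.001245)

estimate_att(gen$dataset, "gcomp", bootstrap_b = 100, seed = 2)
#> <att_estimate> gcomp: ATT = 0.2610 (se 0.0969, 95% CI [0.0956, 0.4208], p = 0.007037)

estimate_att(gen$dataset, "ddml", n_splits = 5, seed = 3)
#> <att_estimate> ddml: ATT = 0.2858 (se 0.1122, 95% CI [0.0659, 0.5056], p = 0.01085)
```

The unadjusted contrast (0.42) overstates the true ATT (0.26) by the
confounding bias; G-computation (0.26) and DDML (0.29) recover it, with
G-computation giving the tighter interval — the pattern the full
benchmark quantifies.

The numbered scripts under `analysis/` run the full studies and write
tidy tables under `results/`:

```sh
Rscript analysis/01_simulate_type1.R   # type I error, n in {250, 1000}
Rscript analysis/02_simulate_power.R   # bias / MSE / CI width / power
Rscript analysis/03_replication.R      # synthetic trial-pool replication
```

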