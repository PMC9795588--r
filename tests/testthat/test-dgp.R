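test_that("sparse SPD covariance generator is positive definite in every draw", {
  expect_gt(drop(make_sparse_spd_covariance(1, 0.5, seed = 1)), 0)
  # full sparsity leaves only the unit diagonal factor
  expect_equal(make_sparse_spd_covariance(6, 1, seed = 2), diag(6))
  set.seed(42)
  min_eig <- replicate(200, {
    s <- make_sparse_spd_covariance(20, 0.8)
    expect_true(isSymmetric(s))
    min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  })
  expect_true(all(min_eig > 0))
})

test_that("sparsity parameter controls the covariance factor structure", {
  # alpha = 0.8 should leave roughly 20% of off-diagonal factor entries
  # active; the covariance then has many exact zeros off the diagonal
  set.seed(7)
  s <- make_sparse_spd_covariance(30, 0.95)
  off <- s[upper.tri(s)]
  expect_gt(mean(off == 0), 0.5)
})

test_that("covariate sampler reproduces the requested covariance", {
  X <- sample_covariates(10000, diag(3), seed = 5)
  expect_equal(dim(X), c(10000L, 3L))
  expect_lt(max(abs(crossprod(X) / 10000 - diag(3))), 0.1)
  expect_equal(dim(sample_covariates(1, diag(4), seed = 1)), c(1L, 4L))
  cov2 <- matrix(c(1, 0.9, 0.9, 1), 2)
  X2 <- sample_covariates(10000, cov2, seed = 6)
  expect_equal(cor(X2)[1, 2], 0.9, tolerance = 0.05)
})

test_that("exposure model gives the stated propensities", {
  X <- matrix(rnorm(50), 10, 5)
  tr <- sample_treatment(X, rep(0, 5), seed = 1)
  expect_equal(tr$propensity, rep(0.5, 10))
  X0 <- matrix(0, 3, 5)
  expect_equal(sample_treatment(X0, runif(5, -1, 1), seed = 2)$propensity,
               rep(0.5, 3))
  # beta = (sqrt(5),0,0,0,0), x1 = 1 => logit = 1
  X1 <- matrix(c(1, 0, 0, 0, 0), 1, 5)
  expect_equal(sample_treatment(X1, c(sqrt(5), 0, 0, 0, 0), seed = 3)$propensity,
               1 / (1 + exp(-1)), tolerance = 1e-10)
})

test_that("scenario-1 outcomes follow the sparse linear model", {
  X <- matrix(0, 6, 20)
  t <- c(1L, 1L, 0L, 0L, 1L, 0L)
  y <- sample_outcome_scenario1(X, t, 1:20, theta = 1, noise_sd = 0)
  expect_equal(y, as.numeric(t))
  X1 <- matrix(1, 4, 20)
  y1 <- sample_outcome_scenario1(X1, rep(0L, 4), 1:20, theta = 0, noise_sd = 0)
  expect_equal(y1, rep(sqrt(10), 4))
  expect_error(sample_outcome_scenario1(matrix(0, 2, 5), c(0L, 1L), 1:5, 1),
               "covariates")
})

test_that("scenario-1 treatment effect is homogeneous and confounding is real", {
  set.seed(11)
  # potential-outcome difference is theta for every unit
  X <- matrix(rnorm(200 * 20), 200, 20)
  om <- sample.int(20)
  y1 <- sample_outcome_scenario1(X, rep(1L, 200), om, theta = 0.7, seed = 3)
  y0 <- sample_outcome_scenario1(X, rep(0L, 200), om, theta = 0.7, seed = 3)
  expect_equal(y1 - y0, rep(0.7, 200))
  # with beta != 0 the unadjusted contrast is biased away from theta
  gen <- generate_dataset(scenario_config(1, n = 50000, seed = 99))
  unadj <- estimate_unadjusted(gen$dataset)
  expect_gt(abs(unadj - gen$truth$theta), 0.02)
})

test_that("randomized draws (beta = 0) leave the unadjusted estimator unbiased", {
  set.seed(77)
  errs <- vapply(1:300, function(r) {
    X <- sample_covariates(200, diag(20))
    tr <- sample_treatment(X, rep(0, 5))
    if (sum(tr$t) < 2L || sum(1L - tr$t) < 2L) return(NA_real_)
    y <- sample_outcome_scenario1(X, tr$t, sample.int(20), theta = 0.5)
    estimate_unadjusted(eca_dataset(X, tr$t, y)) - 0.5
  }, numeric(1))
  errs <- errs[!is.na(errs)]
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))
})

test_that("scenario-2 draws realize the target in-sample ATT exactly", {
  set.seed(21)
  X <- matrix(rnorm(100 * 20), 100, 20)
  t <- rbinom(100, 1L, 0.5); t[1:2] <- 1L
  om <- sample.int(20)
  # identical permutations: heterogeneous terms cancel, theta = target
  out_same <- sample_outcome_scenario2(X, t, om, om, att_target = 0.3, seed = 4)
  expect_equal(out_same$theta, 0.3)
  om0 <- sample.int(20); om1 <- sample.int(20)
  out <- sample_outcome_scenario2(X, t, om0, om1, att_target = -0.4, seed = 5)
  # treated-average potential-outcome difference (shared noise cancels)
  po_diff <- out$f1 + out$theta - out$f0
  expect_equal(mean(po_diff[t == 1L]), -0.4, tolerance = 1e-12)
  expect_error(sample_outcome_scenario2(X, rep(0L, 100), om0, om1, 0),
               "treated")
})

test_that("dataset generation is deterministic and honors the null", {
  cfg <- scenario_config(2, n = 300, seed = 17)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1$dataset, g2$dataset)
  expect_identical(g1$truth$theta, g2$truth$theta)
  gnull <- generate_dataset(scenario_config(1, n = 300,
                                            null_hypothesis = TRUE, seed = 18))
  expect_identical(gnull$truth$att, 0)
  g2null <- generate_dataset(scenario_config(2, n = 300,
                                             null_hypothesis = TRUE, seed = 19))
  expect_identical(g2null$truth$att, 0)
})

test_that("effect sizes are drawn with variance 0.4 under the alternative", {
  thetas <- vapply(1:300, function(r) {
    generate_dataset(scenario_config(1, n = 20, d = 10,
                                     seed = derive_seed(23, r)))$truth$theta
  }, numeric(1))
  # chi-square interval for a sample variance of 0.4 at 300 draws
  expect_gt(var(thetas), 0.25)
  expect_lt(var(thetas), 0.55)
})

test_that("dataset CSV round-trips and is byte-stable for a fixed seed", {
  gen <- generate_dataset(scenario_config(1, n = 50, d = 5,
                                          n_outcome_covariates = 5,
                                          n_exposure_covariates = 3,
                                          seed = 31))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(gen$dataset, f1)
  write_dataset_csv(generate_dataset(scenario_config(
    1, n = 50, d = 5, n_outcome_covariates = 5, n_exposure_covariates = 3,
    seed = 31))$dataset, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_dataset_csv(f1)
  expect_equal(back$y, gen$dataset$y, tolerance = 1e-12)
  expect_identical(back$t, gen$dataset$t)
})

test_that("trial pool has the stated combinatorics and confounding behavior", {
  pool <- generate_trial_pool(n_trials = 2, arms_per_trial = 2,
                              n_per_arm = 60, shift_scale = 0.5, seed = 41)
  expect_length(build_comparisons(pool, "negative_control"), 4L) # 2 per label
  expect_length(build_comparisons(pool, "rct_replication"), 2L)
  expect_equal(sqrt(sum(pool$shift_magnitudes[[1]]^2)), 0.5, tolerance = 1e-12)
  # unadjusted pseudo-bias grows with the shift on average
  mean_abs_bias <- vapply(c(0, 1.5, 4), function(s) {
    biases <- vapply(1:8, function(r) {
      p <- generate_trial_pool(2, 2, n_per_arm = 100, shift_scale = s,
                               seed = derive_seed(43, round(10 * s), r))
      cmp <- build_comparisons(p, "negative_control")
      mean(vapply(cmp, function(cc) abs(estimate_unadjusted(cc$dataset)),
                  numeric(1)))
    }, numeric(1))
    mean(biases)
  }, numeric(1))
  expect_true(all(diff(mean_abs_bias) > 0))
})

test_that("trial pool serializes through CSVs plus manifest", {
  pool <- generate_trial_pool(2, 2, n_per_arm = 20, shift_scale = 1, seed = 47)
  dir <- withr::local_tempdir()
  write_trial_pool(pool, dir)
  back <- read_trial_pool(dir)
  expect_equal(back$theta, pool$theta, tolerance = 1e-12)
  expect_equal(back$trials[[1]]$arms$control$y, pool$trials[[1]]$arms$control$y,
               tolerance = 1e-12)
  expect_equal(back$omega, pool$omega)
})
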