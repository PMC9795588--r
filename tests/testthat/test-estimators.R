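test_that("unadjusted estimator is the difference in arm means", {
  expect_equal(estimate_unadjusted(toy_dataset(c(3, 1, 0, 0), c(1L, 0L, 1L, 0L))),
               1)
  expect_equal(estimate_unadjusted(toy_dataset(c(5, 3, 2, 0), c(1L, 1L, 0L, 0L))),
               3)
})

test_that("IPTW matches the hand-computed formula and the constant-propensity identity", {
  d <- toy_dataset(c(2, 4, 1, 3), c(1L, 1L, 0L, 0L))
  expect_equal(estimate_iptw(d, c(0.5, 0.5, 0.5, 0.8)), -3.5)
  # constant propensity at the treated fraction reduces to the unadjusted
  # contrast, exactly
  set.seed(1)
  d2 <- randomized_dataset(80, theta = 0.5, seed = 2)
  e_const <- rep(mean(d2$t), 80)
  expect_identical(all.equal(estimate_iptw(d2, e_const),
                             estimate_unadjusted(d2), tolerance = 1e-12), TRUE)
  # vanishing control propensities: estimator tends to the treated mean
  e_small <- ifelse(d2$t == 1L, 0.5, 1e-9)
  expect_equal(estimate_iptw(d2, e_small), mean(d2$y[d2$t == 1L]),
               tolerance = 1e-6)
  expect_error(estimate_iptw(d2, rep(1, 80)), "strictly")
})

test_that("greedy matching follows the documented hand trace", {
  m <- match_greedy(c(0.30, 0.60), c(0.31, 0.90), caliper = 0.25)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(unname(m$pairs[1, ]), c(1L, 1L))
  expect_equal(m$discarded_treated, 2L)
  # identical score lists: perfect matching at zero distance
  m2 <- match_greedy(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8), caliper = 0.25)
  expect_equal(nrow(m2$pairs), 3L)
  expect_equal(m2$distances, rep(0, 3))
  # distances are non-decreasing in selection order
  set.seed(3)
  m3 <- match_greedy(runif(40), runif(40), caliper = 1)
  expect_true(all(diff(m3$distances) >= 0))
})

test_that("greedy matching equals the brute-force oracle on small instances", {
  set.seed(4)
  for (rep in 1:60) {
    n1 <- sample(1:6, 1); n0 <- sample(1:6, 1)
    pt <- round(runif(n1), 2)  # rounding induces ties to exercise tie-breaks
    pc <- round(runif(n0), 2)
    cal <- sample(c(0.05, 0.25, 2), 1)
    got <- match_greedy(pt, pc, caliper = cal)
    want <- oracle_greedy_match(pt, pc, caliper = cal)
    expect_equal(unname(got$pairs), unname(want),
                 info = sprintf("rep %d", rep))
    expect_true(all(got$distances <= cal))
    expect_false(any(duplicated(got$pairs[, 1])))
    expect_false(any(duplicated(got$pairs[, 2])))
  }
  # caliper wide open with equal arms: every treated unit is matched
  set.seed(5)
  m <- match_greedy(runif(6), runif(6), caliper = 100)
  expect_equal(nrow(m$pairs), 6L)
})

test_that("PSM averages within-pair differences and flags non-overlap", {
  d <- toy_dataset(c(2, 0, 1, 3), c(1L, 1L, 0L, 0L))
  e <- c(0.40, 0.60, 0.41, 0.61)  # forces pairs (1,1) and (2,2)
  res <- estimate_psm(d, e, caliper = 0.25)
  expect_equal(res$att, ((2 - 1) + (0 - 3)) / 2)
  expect_equal(nrow(res$match$pairs), 2L)
  # matched controls identical in outcome: estimate 0
  d0 <- toy_dataset(c(1, 2, 1, 2), c(1L, 1L, 0L, 0L))
  expect_equal(estimate_psm(d0, c(0.3, 0.7, 0.3, 0.7))$att, 0)
  expect_error(estimate_psm(d, c(0.1, 0.1, 0.9, 0.9), caliper = 0.25),
               "non-overlap")
})

test_that("G-computation recovers theta exactly with an oracle outcome model", {
  d <- toy_dataset(c(3, 2, 5, 7), c(1L, 1L, 0L, 0L))
  expect_equal(estimate_gcomp(d, function(X) rep(0, nrow(X))), 2.5)
  hand <- toy_dataset(c(3, 2, 0, 0), c(1L, 1L, 0L, 0L))
  mu_vals <- c(1, 4)
  expect_equal(estimate_gcomp(hand, function(X) mu_vals), 0)
  # scenario 1, zero noise, oracle mu0: residual is theta for every treated
  set.seed(6)
  X <- matrix(rnorm(100 * 20), 100, 20)
  t <- rep(c(1L, 0L), 50)
  om <- sample.int(20)
  y <- sample_outcome_scenario1(X, t, om, theta = 0.37, noise_sd = 0)
  d1 <- eca_dataset(X, t, y)
  oracle_mu0 <- function(Xn) rowSums(Xn[, om[1:10], drop = FALSE]) / sqrt(10)
  expect_equal(estimate_gcomp(d1, oracle_mu0), 0.37, tolerance = 1e-12)
})

test_that("scenario-2 null is recovered by G-computation with the oracle model", {
  set.seed(7)
  X <- matrix(rnorm(200 * 20), 200, 20)
  t <- rep(c(1L, 0L), 100)
  om0 <- sample.int(20); om1 <- sample.int(20)
  out <- sample_outcome_scenario2(X, t, om0, om1, att_target = 0, noise_sd = 0)
  d <- eca_dataset(X, t, out$y)
  oracle_mu0 <- function(Xn) rowSums(Xn[, om0[1:10], drop = FALSE]) / sqrt(10)
  expect_equal(estimate_gcomp(d, oracle_mu0), 0, tolerance = 1e-12)
})

test_that("the DDML fold score matches hand computation and the zero-residual identity", {
  # 6 units, e = 0.5 everywhere (odds 1): correction is the summed control
  # residual over the treated count
  y <- c(3, 2, 1, 0, 2, 1)
  t <- c(1L, 1L, 0L, 0L, 0L, 0L)
  mu0 <- c(1, 1, 0, 1, 1, 0)
  sc <- ecabench:::ddml_fold_score(y, t, mu0, rep(0.5, 6))
  gc_aux <- mean((y - mu0)[t == 1L])           # 1.5
  corr <- sum((y - mu0)[t == 0L]) / sum(t)     # 2 / 2
  expect_equal(sc$sum_psi / sc$n1, gc_aux - corr)
  expect_equal(sc$sum_psi / sc$n1, 0.5)
  # zero control residuals: DDML reduces to G-computation on the fold
  mu_exact <- ifelse(t == 0L, y, 0.4)
  sc2 <- ecabench:::ddml_fold_score(y, t, mu_exact, runif(6, 0.2, 0.8))
  expect_equal(sc2$sum_psi / sc2$n1, mean((y - mu_exact)[t == 1L]))
})

test_that("estimators are invariant to row permutation given fixed predictions", {
  set.seed(8)
  d <- randomized_dataset(60, theta = 0.3, seed = 9)
  e <- runif(60, 0.2, 0.8)
  mu <- rnorm(60)
  perm <- sample(60)
  dp <- eca_dataset(d$X[perm, ], d$t[perm], d$y[perm])
  expect_equal(estimate_unadjusted(dp), estimate_unadjusted(d))
  expect_equal(estimate_iptw(dp, e[perm]), estimate_iptw(d, e))
  mu_fun <- function(vals) function(X) vals
  expect_equal(
    estimate_gcomp(dp, mu_fun(mu[perm][dp$t == 1L])),
    estimate_gcomp(d, mu_fun(mu[d$t == 1L])))
  expect_equal(estimate_psm(dp, e[perm])$att, estimate_psm(d, e)$att)
})

test_that("the estimate_att front door dispatches and validates", {
  set.seed(10)
  d <- randomized_dataset(120, theta = 0, seed = 11)
  est <- estimate_att(d, "unadjusted", bootstrap_b = 50, seed = 12)
  expect_s3_class(est, "att_estimate")
  expect_true(est$ci_low <= est$att && est$att <= est$ci_high)
  expect_true(est$p_value >= 0 && est$p_value <= 1)
  expect_error(estimate_att(d, "tmle"), "arg")
})
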