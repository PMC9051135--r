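# univariable two-sample MR estimators

test_that("wald ratio is the exact effect quotient", {
  w1 <- wald_ratio(0.5, 0.05, 0.25, 0.10)
  expect_equal(w1$theta, 0.5)
  expect_equal(w1$se, 0.2)
  w2 <- wald_ratio(1.0, 0.2, 0.0, 0.1)
  expect_equal(w2$theta, 0)
  expect_equal(w2$se, 0.1)
  w3 <- wald_ratio(-0.5, 0.05, 0.25, 0.10)
  expect_equal(w3$theta, -0.5)
  expect_equal(w3$se, 0.2)
  expect_error(wald_ratio(0, 0.1, 0.2, 0.1), "undefined ratio")
})

test_that("IVW reduces to the Wald ratio for one variant and fits exactly", {
  d1 <- harmonized_data(0.5, 0.05, 0.25, 0.10)
  ivw1 <- mr_ivw(d1, effects_model = "fixed")
  w <- wald_ratio(0.5, 0.05, 0.25, 0.10)
  expect_equal(ivw1$theta, w$theta)
  expect_equal(ivw1$se, w$se)
  # exact proportionality: theta recovered, Q = 0
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  d5 <- harmonized_data(bx, rep(0.02, 5), 0.7 * bx, rep(0.05, 5))
  ivw5 <- mr_ivw(d5)
  expect_equal(ivw5$theta, 0.7)
  expect_equal(ivw5$Q, 0)
  expect_equal(ivw5$I2, 0)
  expect_error(mr_ivw(harmonized_data(c(0, 0), c(1, 1), c(1, 1), c(1, 1))),
               "zero")
})

test_that("IVW matches the origin-constrained WLS oracle", {
  for (seed in 1:10) {
    d <- random_uni_dataset(6, seed)
    w <- 1 / d$se_y^2
    want <- oracle_wls(matrix(d$beta_x, ncol = 1), d$beta_y, w, df_resid = 5)
    got <- mr_ivw(d)
    expect_equal(got$theta, want$coef, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
    expect_equal(got$Q, want$Q, tolerance = 1e-10)
    # fixed-effect model never exceeds the random-effects SE
    expect_lte(mr_ivw(d, "fixed")$se, got$se)
  }
})

test_that("Egger recovers an exact linear law and is orientation invariant", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  d <- harmonized_data(bx, rep(0.02, 6), 0.1 + 0.6 * bx, rep(0.05, 6))
  e <- mr_egger(d)
  expect_equal(e$intercept, 0.1)
  expect_equal(e$theta, 0.6)
  expect_equal(e$Q, 0)

  # jointly negating any subset of variants leaves (alpha, theta) unchanged
  set.seed(4)
  d2 <- random_uni_dataset(8, 4)
  base <- mr_egger(d2)
  for (rep in 1:5) {
    flip <- sample(c(TRUE, FALSE), 8, replace = TRUE)
    d3 <- harmonized_data(ifelse(flip, -d2$beta_x, d2$beta_x), d2$se_x,
                          ifelse(flip, -d2$beta_y, d2$beta_y), d2$se_y)
    e3 <- mr_egger(d3)
    expect_equal(e3$theta, base$theta)
    expect_equal(e3$intercept, base$intercept)
    expect_equal(e3$se, base$se)
  }
  expect_error(mr_egger(harmonized_data(c(1, 2), c(1, 1), c(1, 2), c(1, 1))),
               "at least 3")
  same <- harmonized_data(rep(0.3, 4), rep(0.02, 4), rnorm(4), rep(0.05, 4))
  expect_error(mr_egger(same), "unidentified")
})

test_that("Egger matches the intercept-including WLS oracle", {
  for (seed in 11:20) {
    d <- random_uni_dataset(8, seed)
    flip <- d$beta_x < 0
    bx <- ifelse(flip, -d$beta_x, d$beta_x)
    by <- ifelse(flip, -d$beta_y, d$beta_y)
    want <- oracle_wls(cbind(1, bx), by, 1 / d$se_y^2, df_resid = 6)
    got <- mr_egger(d)
    expect_equal(got$intercept, want$coef[1], tolerance = 1e-10)
    expect_equal(got$theta, want$coef[2], tolerance = 1e-10)
    expect_equal(got$se_intercept, want$se[1], tolerance = 1e-10)
    expect_equal(got$se, want$se[2], tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the cumulative weight function", {
  # equal weights, ratios {0.2, 0.5, 0.9} -> plain median
  d <- harmonized_data(c(1, 1, 1), rep(0.01, 3), c(0.2, 0.5, 0.9),
                       rep(0.1, 3))
  expect_equal(mr_weighted_median(d, n_boot = 10, seed = 1)$theta, 0.5)

  # 4 variants with specified weights vs the enumeration oracle
  bx <- c(0.5, 0.25, 1, 2)
  sy <- c(0.1, 0.05, 0.4, 0.2)
  by <- c(0.1, 0.15, 0.3, 1.2)
  d4 <- harmonized_data(bx, rep(0.01, 4), by, sy)
  got <- mr_weighted_median(d4, n_boot = 10, seed = 1)
  expect_equal(got$theta, oracle_weighted_median(by / bx, (bx / sy)^2))

  # random datasets agree with the oracle too
  for (seed in 1:10) {
    dr <- random_uni_dataset(7, seed)
    expect_equal(
      mr_weighted_median(dr, n_boot = 5, seed = 2)$theta,
      oracle_weighted_median(dr$beta_y / dr$beta_x,
                             (dr$beta_x / dr$se_y)^2))
  }
})

test_that("weighted median resists a minority of invalid instruments", {
  set.seed(55)
  bx <- runif(7, 0.2, 0.5)
  by <- 0.5 * bx
  by[6:7] <- 5.0 * bx[6:7]  # two outliers, < 50% of total weight
  sy <- rep(0.05, 7)
  d <- harmonized_data(bx, rep(0.02, 7), by, sy)
  est <- mr_weighted_median(d, n_boot = 500, seed = 99)
  expect_lt(abs(est$theta - 0.5), 1.96 * est$se + 0.1)
  expect_lt(est$theta, 1)  # nowhere near the contaminant slope of 5
})

test_that("weighted median excludes zero-exposure variants and is seeded", {
  d <- harmonized_data(c(0, 0.5, 0.4, 0.3), rep(0.02, 4),
                       c(0.1, 0.25, 0.2, 0.15), rep(0.05, 4))
  expect_warning(est <- mr_weighted_median(d, n_boot = 50, seed = 5),
                 "excluded")
  expect_equal(est$n_snps, 3L)
  # determinism under seed, difference across seeds
  d2 <- random_uni_dataset(6, 3)
  a <- mr_weighted_median(d2, n_boot = 200, seed = 11)
  b <- mr_weighted_median(d2, n_boot = 200, seed = 11)
  c_ <- mr_weighted_median(d2, n_boot = 200, seed = 12)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c_$se))
})

test_that("heterogeneity statistics follow their definitions", {
  bx <- c(0.1, 0.2, 0.3)
  d <- harmonized_data(bx, rep(0.02, 3), 0.7 * bx, rep(0.05, 3))
  het <- heterogeneity(d, 0.7)
  expect_equal(het$Q, 0)
  expect_equal(het$I2, 0)

  # J = 2: hand-computed residual sum
  d2 <- harmonized_data(c(0.2, 0.4), c(0.02, 0.02), c(0.15, 0.1),
                        c(0.1, 0.2))
  het2 <- heterogeneity(d2, 0.5, n_params = 1)
  hand <- (0.15 - 0.5 * 0.2)^2 / 0.1^2 + (0.1 - 0.5 * 0.4)^2 / 0.2^2
  expect_equal(het2$Q, hand)
  expect_equal(het2$df, 1)

  # Q below df floors I2 at 0
  d3 <- harmonized_data(c(0.2, 0.4, 0.3), rep(0.02, 3),
                        c(0.100, 0.201, 0.149), rep(1, 3))
  het3 <- heterogeneity(d3, 0.5)
  expect_lt(het3$Q, het3$df)
  expect_equal(het3$I2, 0)
})

test_that("every estimate is exp-consistent across log-odds and OR scales", {
  d <- random_uni_dataset(10, 42)
  for (est in list(mr_ivw(d), mr_egger(d),
                   mr_weighted_median(d, n_boot = 20, seed = 1))) {
    expect_identical(est$or, exp(est$theta))
    expect_identical(est$or_ci_low, exp(est$ci_low))
    expect_identical(est$or_ci_high, exp(est$ci_high))
    expect_true(est$ci_low < est$theta && est$theta < est$ci_high)
  }
})

test_that("estimators cover the truth on clean simulator output", {
  # pared-down coverage audit (the full 200-replicate version runs in the
  # acceptance suite): no pleiotropy, independent instruments
  theta <- log(2)
  hits <- 0L
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    sim <- simulate_summary_pair(sim_config(
      n_instruments = c(x = 50), true_effects = c(x = theta),
      frac_allele_swapped = 0, frac_palindromic = 0, seed = 1000 + r))
    d <- harmonized_data(sim$exposures$x$beta, sim$exposures$x$se,
                         sim$outcome$beta, sim$outcome$se)
    est <- mr_ivw(d)
    hits <- hits + (est$ci_low <= theta && theta <= est$ci_high)
  }
  expect_gte(hits / n_rep, 0.85)
})

test_that("directional pleiotropy biases IVW but not the Egger slope", {
  # pared-down version of the acceptance property
  theta <- log(2)
  ivw_est <- egger_est <- egger_rej <- numeric(40)
  for (r in 1:40) {
    sim <- simulate_summary_pair(sim_config(
      n_instruments = c(x = 80), true_effects = c(x = theta),
      pleiotropy = "directional", pleiotropy_mean = 0.002,
      pleiotropy_sd = 0.001,
      frac_allele_swapped = 0, frac_palindromic = 0, seed = 3000 + r))
    d <- harmonized_data(sim$exposures$x$beta, sim$exposures$x$se,
                         sim$outcome$beta, sim$outcome$se)
    ivw_est[r] <- mr_ivw(d)$theta
    e <- mr_egger(d)
    egger_est[r] <- e$theta
    egger_rej[r] <- e$pval_intercept < 0.05
  }
  mc_se <- sd(egger_est) / sqrt(40)
  expect_lt(abs(mean(egger_est) - theta), 4 * mc_se)
  expect_gt(mean(ivw_est), theta)  # biased towards the pleiotropy direction
  expect_gt(mean(egger_rej), 0.5)  # intercept test has power
})
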