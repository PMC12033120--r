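test_that("permutation p-value honours its formula bounds", {
  set.seed(41)
  n <- 5e4; m <- 30
  # no outcome signal at all: tau_hat = 0 and every permutation ties it
  panel0 <- make_panel(m, n, b_std = runif(m, 0.05, 0.1), g_std = 0,
                       noise = FALSE)
  fit0 <- mr_lova(panel0)
  expect_equal(permutation_test(panel0, fit0, n_perm = 1, seed = 1), 1)

  # with mixed-sign exposure effects a strong causal signal separates
  # completely from the shuffled null: the minimum p is attained
  m2 <- 100
  b2 <- rnorm(m2, 0, 0.075)
  panel2 <- mr_panel(paste0("mx", 1:m2), b2 + rnorm(m2, 0, 1 / sqrt(n)),
                     1 / sqrt(n), 0.2 * b2 + rnorm(m2, 0, 1 / sqrt(n)),
                     1 / sqrt(n), n, n)
  fit2 <- mr_lova(panel2, p_exposure = 1)
  expect_equal(permutation_test(panel2, fit2, n_perm = 99, seed = 1),
               1 / 100)

  # with one-signed instruments and proportional outcome effects the
  # shuffled slope stays positive and the refit re-selects concordant
  # subsets, so the null is conservative: p is small but does not reach
  # the minimum (the documented power cost of the permutation)
  panel1 <- make_panel(m2, n, b_std = runif(m2, 0.05, 0.1), g_std = 0)
  panel1$g_hat <- 0.2 * panel1$b_hat + rnorm(m2, 0, 1 / sqrt(n))
  fit1 <- mr_lova(panel1)
  p_one <- permutation_test(panel1, fit1, n_perm = 99, seed = 1)
  expect_gt(p_one, 1 / 100)
  expect_lt(p_one, 1)
})

test_that("permutation p-values are uniform under the null and seed-stable", {
  set.seed(42)
  n <- 1e4; m <- 40
  pvals <- replicate(200, {
    panel <- make_panel(m, n, b_std = runif(m, 0.1, 0.15), g_std = 0)
    fit <- mr_lova(panel, n_perm = 99, seed = sample.int(1e6, 1))
    fit$perm_pvalue
  })
  # ties are expected on the discrete (1 + k)/(B + 1) grid
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)

  # same seed reproduces the p-value exactly; different seeds agree to
  # binomial Monte Carlo error
  panel <- make_panel(m, n, b_std = runif(m, 0.1, 0.15), g_std = 0)
  fit <- mr_lova(panel)
  p_a <- permutation_test(panel, fit, n_perm = 199, seed = 7)
  p_b <- permutation_test(panel, fit, n_perm = 199, seed = 7)
  p_c <- permutation_test(panel, fit, n_perm = 199, seed = 8)
  expect_identical(p_a, p_b)
  expect_lt(abs(p_a - p_c), 0.2)
})

test_that("directional pleiotropy t-test: symmetry, equivariance, calibration, power", {
  sym <- directional_pleiotropy_test(c(0.2, -0.2, 0.2, -0.2))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$pvalue, 1)
  expect_equal(sym$df, 3)

  # scale equivariance: positive rescaling leaves t and p unchanged
  set.seed(43)
  u <- rnorm(30, 0.05, 0.1)
  expect_equal(directional_pleiotropy_test(u),
               directional_pleiotropy_test(17.3 * u))

  expect_error(directional_pleiotropy_test(rep(0.1, 5)), "constant")
  expect_error(directional_pleiotropy_test(0.1), "at least 2")

  # type-I calibration under balanced pleiotropy draws
  rej_null <- mean(replicate(1000,
    directional_pleiotropy_test(rnorm(100, 0, 0.15))$pvalue < 0.05))
  band <- qbinom(c(0.005, 0.995), 1000, 0.05) / 1000
  expect_gte(rej_null, band[1])
  expect_lte(rej_null, band[2])

  # power under directional pleiotropy draws
  rej_alt <- mean(replicate(500,
    directional_pleiotropy_test(rnorm(100, 0.1, 0.075))$pvalue < 0.05))
  expect_gte(rej_alt, 0.98)
})

test_that("InSIDE test: perfect correlation, affine invariance, calibration, power", {
  b <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  perfect <- inside_test(2 * b, b)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$df, 3)

  set.seed(44)
  u <- rnorm(50); bb <- rnorm(50)
  base <- inside_test(u, bb)
  resc <- inside_test(3 * u + 1, -2 * bb + 5)
  expect_equal(abs(resc$r), abs(base$r))
  expect_equal(resc$pvalue, base$pvalue)

  expect_error(inside_test(rep(1, 5), b), "constant")
  expect_error(inside_test(u, bb[1:10]), "same length")

  # type-I calibration with independent u and b
  rej_null <- mean(replicate(1000,
    inside_test(rnorm(100, 0, 0.1), runif(100, 0.05, 0.2))$pvalue < 0.05))
  band <- qbinom(c(0.005, 0.995), 1000, 0.05) / 1000
  expect_gte(rej_null, band[1])
  expect_lte(rej_null, band[2])

  # power under a genetic confounder: direct effects computed at the true
  # tau = 0 correlate with the exposure effects through phi
  cfg <- sim_config(scenario = 4, m = 100, n = 10000, prop_invalid = 0.7,
                    theta = 0.7)
  hits <- replicate(11, {
    eff <- draw_true_effects(cfg)
    co1 <- simulate_cohort(eff, cfg)
    co2 <- simulate_cohort(eff, cfg)
    panel <- standardize_panel(harmonize(gwas_summary(co1, "exposure"),
                                         gwas_summary(co2, "outcome"),
                                         verbose = FALSE))
    inside_test(panel$g_hat, panel$b_hat)$pvalue < 0.05
  })
  expect_gte(mean(hits), 0.6)
})

test_that("diagnostics wrapper uses all instruments at the converged tau", {
  set.seed(45)
  n <- 2e4; m <- 50
  panel <- make_panel(m, n, b_std = runif(m, 0.05, 0.12), g_std = 0)
  fit <- mr_lova(panel, p_exposure = 1)
  d <- mr_diagnostics(fit)
  expect_s3_class(d, "mr_diagnostics")
  expect_equal(d$n_snps_used, m)
  expect_equal(d$dir_pleio_df, m - 1)
  oracle <- t.test(fit$u_hat)$p.value
  expect_equal(d$dir_pleio_p, oracle)
})

test_that("IVW and Egger baselines match weighted-least-squares oracles", {
  n <- 1e4
  b <- c(0.05, 0.08, 0.1, 0.12, 0.15)
  # exact proportionality: slope is tau, Egger intercept vanishes
  prop <- mr_panel(paste0("p", 1:5), b, 1 / sqrt(n), 0.3 * b,
                   c(0.010, 0.011, 0.009, 0.012, 0.010), n, n)
  expect_equal(mr_ivw(prop)$tau_hat, 0.3, tolerance = 1e-12)
  egger0 <- mr_egger(prop)
  expect_equal(egger0$tau_hat, 0.3, tolerance = 1e-10)
  expect_equal(egger0$intercept, 0, tolerance = 1e-12)

  # a single instrument degenerates to the Wald ratio
  single <- mr_panel("s1", 0.1, 0.01, 0.04, 0.01, n, n)
  expect_equal(mr_ivw(single)$tau_hat, 0.4)
  expect_error(mr_egger(single), "at least 3")

  # generic weights: both match lm() normal equations
  set.seed(46)
  panel <- mr_panel(paste0("q", 1:5), b, 1 / sqrt(n),
                    0.3 * b + rnorm(5, 0, 0.01),
                    c(0.010, 0.013, 0.008, 0.011, 0.012), n, n)
  w <- 1 / panel$se_g^2
  expect_equal(mr_ivw(panel)$tau_hat,
               unname(coef(lm(g_hat ~ 0 + b_hat, panel, weights = w))),
               tolerance = 1e-12)
  eg <- mr_egger(panel)
  lm_fit <- lm(g_hat ~ b_hat, panel, weights = w)
  expect_equal(eg$tau_hat, unname(coef(lm_fit)["b_hat"]), tolerance = 1e-12)
  expect_equal(eg$intercept, unname(coef(lm_fit)["(Intercept)"]),
               tolerance = 1e-12)
})
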