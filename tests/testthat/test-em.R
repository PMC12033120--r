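test_that("cov(y,c) approximation equals the summed effect products", {
  n <- 1e4
  panel0 <- mr_panel(c("a", "b"), b_hat = c(0.2, 0.1),
                     se_b = 0.01, g_hat = c(0, 0), se_g = 0.01,
                     n_exp = n, n_out = n)
  expect_equal(estimate_cov_yc(panel0), 0)
  panel1 <- mr_panel(c("a", "b"), b_hat = c(0.2, 0.15), se_b = 0.01,
                     g_hat = c(0.1, 0), se_g = 0.01, n_exp = n, n_out = n)
  expect_equal(estimate_cov_yc(panel1), 0.02)
  expect_error(estimate_cov_yc(panel1[1, ]), "at least 2")
  big <- mr_panel(c("a", "b"), c(1, 1), 0.01, c(1, 1), 0.01, n, n)
  expect_warning(cv <- estimate_cov_yc(big), "clipped")
  expect_equal(abs(cv), 0.999)
})

test_that("cov(y,c) estimate recovers the phenotypic covariance of the causal model", {
  # cohorts generated from the plain causal model (no shared confounder),
  # so the genetic covariance read off the panel approximates cov(c, y)
  set.seed(11)
  n <- 2e4; m <- 50
  maf <- runif(m, 0.1, 0.3)
  b <- runif(m, 0.1, 0.2)
  u <- c(rnorm(10, 0.2, 0.05), rep(0, m - 10))
  tau <- 0.3
  gen <- function() {
    X <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), n, m)
    c_ <- drop(X %*% b) + rnorm(n)
    y <- c_ * tau + drop(X %*% u) + rnorm(n)
    cohort_data(X, exposure = c_, outcome = y)
  }
  co1 <- gen(); co2 <- gen(); oracle_cohort <- gen()
  panel <- standardize_panel(harmonize(gwas_summary(co1, "exposure"),
                                       gwas_summary(co2, "outcome"),
                                       verbose = FALSE))
  # oracle: the true genetic covariance var-weighted over SNPs,
  # sum_j 2 f_j (1 - f_j) b_j (tau b_j + u_j), on the standardized scale
  gencov <- sum(2 * maf * (1 - maf) * b * (tau * b + u)) /
    (sd(oracle_cohort$c) * sd(oracle_cohort$y))
  expect_equal(estimate_cov_yc(panel), gencov, tolerance = 0.06)
})

test_that("E-step imputes direct effects and their variances", {
  # tau = 0 is the identity on (g_hat, var(g_hat))
  g <- c(0.1, -0.05, 0); b <- c(0.2, 0.1, 0.15); se_g <- rep(0.01, 3)
  es <- e_step(g, b, se_g, tau = 0, cov_yc = 0.3, n_out = 1e4)
  expect_identical(es$u_hat, g)
  expect_identical(es$var_u, se_g^2)

  # direct substitution
  expect_equal(e_step(0.10, 0.20, 0.01, tau = 0.5, cov_yc = 0,
                      n_out = 1e4)$u_hat, 0)
  es2 <- e_step(0.1, 0.2, 0.01, tau = 0.2, cov_yc = 0.3, n_out = 1e4)
  expect_equal(es2$var_u, 9.2e-5)

  # degenerate variances are an error, not silent garbage
  expect_error(e_step(0.1, 0.2, se_g = 1e-6, tau = 1, cov_yc = 0.999,
                      n_out = 10), "cov_yc")
})

test_that("inclusion indicator enforces both exclusion restriction and relevance", {
  n <- 1e4; se <- 1 / sqrt(n)
  # u at zero (p = 1) with strong exposure effect: included
  expect_true(inclusion_indicator(0, se^2, 10 * se, se))
  # weak exposure effect excludes regardless of u
  expect_false(inclusion_indicator(0, se^2, 1 * se, se))
  # significant direct effect on the latent outcome excludes
  expect_false(inclusion_indicator(3 * se, se^2, 10 * se, se))
  # vectorized
  inc <- inclusion_indicator(c(0, 0, 3 * se), rep(se^2, 3),
                             c(10, 1, 10) * se, rep(se, 3))
  expect_equal(inc, c(TRUE, FALSE, FALSE))
})

test_that("M-step equals the weighted normal-equations solve", {
  expect_equal(m_step_ivw(0.05, 1e-4, 0.25, TRUE), 0.2)
  expect_equal(m_step_ivw(c(0, 0, 0), rep(1e-4, 3), c(0.1, 0.2, 0.3),
                          rep(TRUE, 3)), 0)
  expect_error(m_step_ivw(0.1, 1e-4, 0.2, FALSE), "no valid instruments")

  set.seed(5)
  for (i in 1:20) {
    m <- sample(3:30, 1)
    u <- rnorm(m, 0, 0.05)
    b <- runif(m, 0.05, 0.3)
    v <- runif(m, 1e-5, 1e-3)
    inc <- runif(m) > 0.3
    if (!any(inc)) inc[1] <- TRUE
    oracle <- unname(coef(lm(u ~ 0 + b, weights = 1 / v, subset = inc)))
    expect_equal(m_step_ivw(u, v, b, inc), oracle, tolerance = 1e-12)
  }
})

test_that("EM fit handles the null, converges to a fixed point, and respects relevance", {
  set.seed(9)
  n <- 5e4; m <- 60
  # pure null: no outcome signal at all, strong instruments
  panel_null <- make_panel(m, n, b_std = runif(m, 0.05, 0.1), g_std = 0,
                           noise = FALSE)
  fit0 <- mr_lova(panel_null)
  expect_equal(fit0$tau_hat, 0)
  expect_equal(fit0$n_selected, m)
  expect_true(fit0$converged)

  # fixed point: one more E/M cycle at tau_hat moves by less than tol
  panel <- make_panel(m, n, b_std = runif(m, 0.05, 0.1),
                      g_std = 0.2 * runif(m, 0.05, 0.1))
  panel$g_hat <- 0.2 * panel$b_hat + rnorm(m, 0, 1 / sqrt(n))
  fit <- mr_lova(panel)
  expect_true(fit$converged)
  cov_yc <- estimate_cov_yc(panel)
  es <- e_step(panel$g_hat, panel$b_hat, panel$se_g, fit$tau_hat, cov_yc,
               attr(panel, "n_out"))
  inc <- inclusion_indicator(es$u_hat, es$var_u, panel$b_hat, panel$se_b)
  expect_lt(abs(m_step_ivw(es$u_hat, es$var_u, panel$b_hat, inc)),
            fit$params$tol)

  # SNPs failing the relevance threshold never enter the selected set
  mixed <- mr_panel(paste0("w", 1:(m + 10)),
                    b_hat = c(panel$b_hat, rnorm(10, 0, 1 / sqrt(n))),
                    se_b = 1 / sqrt(n),
                    g_hat = c(panel$g_hat, rnorm(10, 0, 1 / sqrt(n))),
                    se_g = 1 / sqrt(n), n_exp = n, n_out = n)
  fit_mixed <- mr_lova(mixed)
  weak_ids <- paste0("w", (m + 1):(m + 10))
  expect_length(intersect(fit_mixed$selected_ids, weak_ids), 0)

  # the trace records every tau update from the initial value
  expect_equal(fit$trace$iteration, 0:fit$n_iter)
  expect_equal(fit$trace$tau[1], 0)
  expect_equal(fit$trace$tau[fit$n_iter + 1], fit$tau_hat)

  # non-convergence within max_iter is flagged, not thrown
  fit_short <- mr_lova(panel, max_iter = 1L)
  expect_false(fit_short$converged)
  expect_s3_class(fit_short, "mr_lova")
})

test_that("the direct M-step reading is available as a sensitivity flag", {
  set.seed(13)
  n <- 5e4; m <- 40
  panel <- make_panel(m, n, b_std = runif(m, 0.05, 0.1), g_std = 0)
  panel$g_hat <- 0.15 * panel$b_hat + rnorm(m, 0, 1 / sqrt(n))
  fit_inc <- mr_lova(panel)
  fit_dir <- mr_lova(panel, mstep = "direct")
  # both readings share the fixed point when the same set is selected
  expect_equal(fit_dir$tau_hat, fit_inc$tau_hat, tolerance = 1e-4)
})
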