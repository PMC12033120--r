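# Simulation framework: four pleiotropy scenarios, two-sample GWAS panels
# with ground truth, and an evaluation harness.
#
# Generative model per cohort (shared MAFs and true effects within a
# replicate, disjoint individuals between the exposure and outcome cohorts):
#   X_ij ~ Binomial(2, f_j),  f_j ~ U(0.1, 0.3)
#   z = X phi + eta          (unobserved confounder; eta ~ N(0, 1))
#   c = X b + z + eps        (exposure; eps ~ N(0, 1))
#   y = c tau + X u + z + e  (outcome; e ~ N(0, 1))
# The confounder z is present in every scenario; phi is non-zero only when
# the InSIDE assumption is violated (scenario 4).

.scenarios <- c("no_pleiotropy", "balanced", "directional", "inside_violated")

#' Simulation configuration
#'
#' Defines one simulation condition. Scenarios: 1 `no_pleiotropy` (all
#' instruments valid), 2 `balanced` (direct effects `u ~ N(0, 0.15)` on the
#' invalid subset), 3 `directional` (`u ~ N(0.1, 0.075)`), 4
#' `inside_violated` (as 3, plus confounder loadings `phi ~ U(0, theta)` on
#' the same invalid subset, inducing `cor(u, b) != 0`). Instrument
#' strengths are drawn from a left-truncated normal: `N(0, 0.1)` truncated
#' at 0.1 for `m = 30`-scale panels, `N(0, 0.05)` truncated at 0.05 for
#' `m = 100`-scale panels.
#'
#' @param scenario Scenario number 1-4 or name (see above).
#' @param m Number of instruments (30 or 100 in the reference settings).
#' @param n Individuals per cohort (10,000 or 50,000 in the reference
#'   settings).
#' @param prop_invalid Proportion of invalid instruments (0, 0.3, 0.5,
#'   0.7); `round(prop_invalid * m)` SNPs receive non-zero `u` (and `phi`
#'   in scenario 4).
#' @param tau_scaled Causal effect on the scale of standardized traits
#'   (0 or 0.2 in the reference settings); converted to the raw-trait
#'   effect by [calibrate_tau()].
#' @param theta Upper bound of the confounder loadings (scenario 4 only;
#'   0.1, 0.4 or 0.7). Ignored, with a warning, in other scenarios.
#' @param maf_range Minor-allele-frequency range; default `c(0.1, 0.3)`.
#' @param pleio_scale Interpret the second parameter of the pleiotropy
#'   distributions as `"sd"` (default) or `"var"`.
#' @param b_sd,b_trunc Override the instrument-strength distribution
#'   (defaults chosen from `m` as above).
#' @return A validated list of class `mr_sim_config`.
#' @export
sim_config <- function(scenario = 1, m = 100L, n = 50000L,
                       prop_invalid = 0, tau_scaled = 0, theta = NULL,
                       maf_range = c(0.1, 0.3),
                       pleio_scale = c("sd", "var"),
                       b_sd = NULL, b_trunc = NULL) {
  if (is.character(scenario)) scenario <- match(scenario, .scenarios)
  if (!scenario %in% 1:4) stop("scenario must be 1-4 or one of: ",
                               paste(.scenarios, collapse = ", "))
  pleio_scale <- match.arg(pleio_scale)
  if (scenario == 4) {
    if (is.null(theta) || theta <= 0)
      stop("scenario 4 (inside_violated) requires theta > 0")
  } else if (!is.null(theta)) {
    warning("theta is ignored outside scenario 4")
    theta <- NULL
  }
  if (m < 2) stop("m must be at least 2")
  if (n < 10) stop("n must be at least 10")
  if (prop_invalid < 0 || prop_invalid > 1)
    stop("prop_invalid must lie in [0, 1]")
  if (scenario > 1 && round(prop_invalid * m) == 0)
    warning("pleiotropy scenario with zero invalid instruments")
  small_m <- m <= 65  # reference settings: 30 vs 100 instruments
  structure(list(scenario = scenario, scenario_name = .scenarios[scenario],
                 m = as.integer(m), n = as.integer(n),
                 prop_invalid = prop_invalid, tau_scaled = tau_scaled,
                 theta = theta, maf_range = maf_range,
                 pleio_scale = pleio_scale,
                 b_sd = b_sd %||% (if (small_m) 0.1 else 0.05),
                 b_trunc = b_trunc %||% (if (small_m) 0.1 else 0.05)),
            class = "mr_sim_config")
}

# Left-truncated normal by rejection sampling (acceptance >= ~16% at the
# reference settings, where the truncation point sits one SD above 0).
rtrunc_normal <- function(n, mean = 0, sd = 1, lower = -Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Draw ground-truth effects for one replicate
#'
#' Draws instrument strengths `b` from the left-truncated normal, assigns
#' a random subset of `round(prop_invalid * m)` SNPs non-zero direct
#' effects `u` (and confounder loadings `phi` in scenario 4; the `u` and
#' `phi` supports coincide, the sterner InSIDE violation), and draws the
#' replicate's MAFs. Uses the current RNG state.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `mr_true_effects` with `b`, `u`, `phi`, `maf`,
#'   `valid` (logical mask `u == 0 & phi == 0`), `snp_ids`.
#' @export
draw_true_effects <- function(config) {
  stopifnot(inherits(config, "mr_sim_config"))
  m <- config$m
  sd_of <- function(par) if (config$pleio_scale == "sd") par else sqrt(par)
  b <- rtrunc_normal(m, 0, config$b_sd, config$b_trunc)
  u <- numeric(m)
  phi <- numeric(m)
  n_invalid <- round(config$prop_invalid * m)
  if (config$scenario > 1 && n_invalid > 0) {
    invalid <- sample.int(m, n_invalid)
    u[invalid] <- if (config$scenario == 2)
      stats::rnorm(n_invalid, 0, sd_of(0.15))
    else
      stats::rnorm(n_invalid, 0.1, sd_of(0.075))
    if (config$scenario == 4)
      phi[invalid] <- stats::runif(n_invalid, 0, config$theta)
  }
  structure(list(b = b, u = u, phi = phi,
                 maf = stats::runif(m, config$maf_range[1],
                                    config$maf_range[2]),
                 valid = u == 0 & phi == 0,
                 snp_ids = paste0("snp", seq_len(m))),
            class = "mr_true_effects")
}

#' Simulate one cohort
#'
#' Generates genotypes and phenotypes from the generative model (see the
#' module header) for the given true effects and raw-scale causal effect.
#'
#' @param effects An [draw_true_effects()] object.
#' @param config The [sim_config()] used to draw `effects`.
#' @param tau_raw Causal effect on the raw trait scale (see
#'   [calibrate_tau()]).
#' @param n Number of individuals; defaults to `config$n`.
#' @return An `mr_cohort` with raw-scale `c` and `y`.
#' @export
simulate_cohort <- function(effects, config, tau_raw = 0, n = NULL) {
  stopifnot(inherits(effects, "mr_true_effects"),
            inherits(config, "mr_sim_config"))
  n <- as.integer(n %||% config$n)
  m <- config$m
  X <- matrix(stats::rbinom(n * m, 2L, rep(effects$maf, each = n)), n, m)
  colnames(X) <- effects$snp_ids
  z <- drop(X %*% effects$phi) + stats::rnorm(n)
  c_ <- drop(X %*% effects$b) + z + stats::rnorm(n)
  y <- c_ * tau_raw + drop(X %*% effects$u) + z + stats::rnorm(n)
  cohort_data(X, exposure = c_, outcome = y, snp_ids = effects$snp_ids)
}

#' Calibrate the raw-scale causal effect
#'
#' The scenario parameter `tau_scaled` is the causal effect when both
#' traits are standardized; on raw traits the effect is
#' `tau_raw = tau_scaled * SD(y) / SD(c)`. Since `SD(y)` itself depends on
#' `tau_raw`, the value is found by fixed-point iteration on a pilot
#' cohort whose genotypes and noise draws are held fixed while `y` is
#' recomputed.
#'
#' @param effects An [draw_true_effects()] object.
#' @param config The matching [sim_config()].
#' @param pilot_n Pilot-cohort size; default 10,000.
#' @param tol Convergence tolerance on `tau_raw`; default `1e-4`.
#' @param max_iter Maximum fixed-point iterations; default 10.
#' @return The raw-scale causal effect (0 when `tau_scaled = 0`).
#' @export
calibrate_tau <- function(effects, config, pilot_n = 10000L, tol = 1e-4,
                          max_iter = 10L) {
  stopifnot(inherits(effects, "mr_true_effects"),
            inherits(config, "mr_sim_config"))
  if (config$tau_scaled == 0) return(0)
  n <- as.integer(pilot_n)
  X <- matrix(stats::rbinom(n * config$m, 2L, rep(effects$maf, each = n)),
              n, config$m)
  z <- drop(X %*% effects$phi) + stats::rnorm(n)
  c_ <- drop(X %*% effects$b) + z + stats::rnorm(n)
  gpart <- drop(X %*% effects$u) + z + stats::rnorm(n)  # y minus c*tau
  sd_c <- stats::sd(c_)
  tau <- config$tau_scaled
  for (i in seq_len(max_iter)) {
    tau_new <- config$tau_scaled * stats::sd(c_ * tau + gpart) / sd_c
    if (abs(tau_new - tau) < tol) return(tau_new)
    tau <- tau_new
  }
  stop("tau calibration did not converge within ", max_iter, " iterations")
}

#' Compute GWAS summary statistics for a simulated cohort
#'
#' Per-SNP simple linear regression of the standardized trait on each
#' standardized dosage, yielding effects on the standardized scale with
#' `se ~ 1/sqrt(n)`. Constant-genotype SNPs are dropped with a warning by
#' the cohort constructor upstream.
#'
#' @param cohort An `mr_cohort`.
#' @param trait `"exposure"` or `"outcome"`.
#' @return An `mr_sumstats` table (alleles coded A/G by construction).
#' @export
gwas_summary <- function(cohort, trait = c("exposure", "outcome")) {
  stopifnot(inherits(cohort, "mr_cohort"))
  trait <- match.arg(trait)
  t_raw <- if (trait == "exposure") cohort$c else cohort$y
  if (is.null(t_raw)) stop("cohort lacks the ", trait, " phenotype")
  n <- nrow(cohort$X)
  if (n < 10) stop("gwas_summary requires at least 10 individuals")
  t_std <- drop(scale(t_raw))
  reg <- snp_regression(std_genotypes(cohort$X), t_std)
  out <- data.frame(snp = cohort$snp_ids,
                    effect_allele = "A", other_allele = "G",
                    beta = reg$beta, se = reg$se,
                    pvalue = z_pvalue(reg$beta / reg$se),
                    n = n, stringsAsFactors = FALSE)
  class(out) <- c("mr_sumstats", "data.frame")
  out
}

# One full replicate: effects -> calibrated tau -> two disjoint cohorts ->
# summary panels -> harmonized standardized panel.
sim_replicate <- function(config) {
  effects <- draw_true_effects(config)
  tau_raw <- calibrate_tau(effects, config)
  exp_cohort <- simulate_cohort(effects, config, tau_raw)
  out_cohort <- simulate_cohort(effects, config, tau_raw)
  panel <- standardize_panel(harmonize(gwas_summary(exp_cohort, "exposure"),
                                       gwas_summary(out_cohort, "outcome"),
                                       verbose = FALSE))
  list(effects = effects, tau_raw = tau_raw, panel = panel,
       exp_cohort = exp_cohort, out_cohort = out_cohort)
}

#' Run a simulation experiment
#'
#' Repeats: draw ground truth, calibrate the raw causal effect, simulate
#' two non-overlapping cohorts, compute and harmonize summary statistics,
#' and apply each estimator. By default every instrument is provided to
#' the estimators (`p_exposure = 1`), mirroring the reference evaluation
#' design in which all `m` SNPs are initially supplied to each method; set
#' `p_exposure = 5e-8` to impose the genome-wide relevance screen instead.
#' A method failure on a replicate is logged and recorded as `NA`.
#'
#' One master `seed` spawns an independent per-replicate seed stream
#' (recorded in the output), so results are reproducible replicate by
#' replicate.
#'
#' @param config An [sim_config()] object.
#' @param reps Number of replicates (>= 1).
#' @param seed Master seed.
#' @param methods Estimators to run: subset of `"mr_lova"`, `"ivw"`,
#'   `"egger"`.
#' @param p_exposure Exposure threshold handed to the estimators (see
#'   above).
#' @param p_outcome Latent-outcome inclusion threshold for MR-LOVA.
#' @return An object of class `mr_experiment`: `replicates` (one row per
#'   replicate x method with `tau_hat`, `se`, `pvalue`, and for MR-LOVA
#'   the confusion counts `tp`, `fp`, `fn`, `tn`, `n_selected` against the
#'   ground-truth validity mask), plus `config`, `seed`, `rep_seeds`.
#' @export
run_experiment <- function(config, reps, seed,
                           methods = c("mr_lova", "ivw", "egger"),
                           p_exposure = 1, p_outcome = 0.05) {
  stopifnot(inherits(config, "mr_sim_config"), reps >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(2147483647L, reps)
  rows <- vector("list", reps * length(methods))
  k <- 0L
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    sim <- sim_replicate(config)
    panel <- sim$panel
    if (p_exposure < 1)
      panel <- relevance_filter(panel, p_exposure, verbose = FALSE)
    valid <- stats::setNames(sim$effects$valid, sim$effects$snp_ids)
    for (method in methods) {
      k <- k + 1L
      row <- data.frame(rep = r, seed = rep_seeds[r], method = method,
                        tau_hat = NA_real_, se = NA_real_,
                        pvalue = NA_real_, tp = NA_real_, fp = NA_real_,
                        fn = NA_real_, tn = NA_real_,
                        n_selected = NA_real_,
                        stringsAsFactors = FALSE)
      fit <- tryCatch(switch(method,
        mr_lova = mr_lova(panel, p_outcome = p_outcome,
                          p_exposure = p_exposure),
        ivw = mr_ivw(panel),
        egger = mr_egger(panel)),
        error = function(e) {
          message("replicate ", r, ", method ", method, " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(fit)) {
        row$tau_hat <- fit$tau_hat
        row$se <- fit$se_tau
        row$pvalue <- fit$pvalue
        if (inherits(fit, "mr_lova")) {
          selected <- names(valid) %in% fit$selected_ids
          row$tp <- sum(selected & valid)
          row$fp <- sum(selected & !valid)
          row$fn <- sum(!selected & valid)
          row$tn <- sum(!selected & !valid)
          row$n_selected <- sum(selected)
        }
      }
      rows[[k]] <- row
    }
  }
  structure(list(replicates = do.call(rbind, rows), config = config,
                 seed = seed, rep_seeds = rep_seeds),
            class = "mr_experiment")
}

#' Summarize a simulation experiment
#'
#' Aggregates per-replicate results into one row per method: rejection
#' rate at `alpha` (type-I error under `tau_scaled = 0`, power otherwise),
#' mean estimate, MSE against `tau_scaled`, and -- for methods that select
#' instruments -- mean confusion counts, sensitivity (valid instruments
#' retained), specificity (invalid instruments excluded), accuracy, and
#' mean number selected, averaged over replicates.
#'
#' @param experiment An [run_experiment()] result.
#' @param alpha Rejection level; default 0.05.
#' @return A `data.frame` with one row per method.
#' @export
summarize_experiment <- function(experiment, alpha = 0.05) {
  stopifnot(inherits(experiment, "mr_experiment"))
  reps <- experiment$replicates
  tau_true <- experiment$config$tau_scaled
  m <- experiment$config$m
  do.call(rbind, lapply(split(reps, reps$method), function(d) {
    ok <- !is.na(d$tau_hat)
    sel <- ok & !is.na(d$tp)
    data.frame(
      method = d$method[1],
      n_reps = sum(ok),
      n_failed = sum(!ok),
      rejection_rate = mean(d$pvalue[ok] < alpha),
      mean_estimate = mean(d$tau_hat[ok]),
      mse = mean((d$tau_hat[ok] - tau_true)^2),
      tp = if (any(sel)) mean(d$tp[sel]) else NA_real_,
      fp = if (any(sel)) mean(d$fp[sel]) else NA_real_,
      fn = if (any(sel)) mean(d$fn[sel]) else NA_real_,
      tn = if (any(sel)) mean(d$tn[sel]) else NA_real_,
      sensitivity = if (any(sel))
        mean(d$tp[sel] / (d$tp[sel] + d$fn[sel])) else NA_real_,
      specificity = if (any(sel))
        mean(d$tn[sel] / (d$tn[sel] + d$fp[sel])) else NA_real_,
      accuracy = if (any(sel))
        mean((d$tp[sel] + d$tn[sel]) / m) else NA_real_,
      mean_selected = if (any(sel)) mean(d$n_selected[sel]) else NA_real_,
      stringsAsFactors = FALSE, row.names = NULL)
  }))
}
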