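# Pleiotropy diagnostics and minimal IVW / MR-Egger baselines.

#' Permutation test for the causal estimate
#'
#' Builds an empirical null for `tau_hat` by jointly shuffling the outcome
#' effect estimates and their standard errors against the exposure effects
#' and re-running the complete EM fit on each shuffled panel. At the
#' initialization `tau = 0` the imputed direct effects equal the outcome
#' effects, so shuffling `(g_hat, se_g)` is exactly a shuffle of the
#' initial `(u_hat, se(u_hat))`; re-running the fit propagates instrument
#' selection uncertainty into the null. The empirical two-sided p-value is
#' `(1 + #\{|tau_perm| >= |tau_obs|\}) / (n_perm + 1)`.
#'
#' @param panel The standardized `mr_panel` the observed fit used.
#' @param observed The observed [mr_lova()] fit.
#' @param n_perm Number of permutations (>= 1); default 1000.
#' @param seed Seed for the permutation stream.
#' @return The empirical p-value.
#' @export
permutation_test <- function(panel, observed, n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(panel, "mr_panel"), inherits(observed, "mr_lova"))
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  p <- observed$params
  omega <- if (!is.null(p$ld)) align_ld(p$ld, panel$snp) else NULL
  m <- nrow(panel)
  tau_perm <- rep(NA_real_, n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(m)
    pp <- panel
    pp$g_hat <- panel$g_hat[idx]
    pp$se_g <- panel$se_g[idx]
    tau_perm[i] <- tryCatch(
      .lova_em(pp, p$tau0, p$tol, p$max_iter, p$p_outcome, p$p_exposure,
               omega, p$mstep)$tau_hat,
      error = function(e) NA_real_)
  }
  failed <- sum(is.na(tau_perm))
  if (failed)
    warning(failed, " of ", n_perm, " permutation fits failed and were ",
            "dropped from the null")
  tau_perm <- tau_perm[!is.na(tau_perm)]
  (1 + sum(abs(tau_perm) >= abs(observed$tau_hat))) / (length(tau_perm) + 1)
}

#' Test for directional pleiotropy
#'
#' One-sample t-test of whether the mean of the direct SNP effects on the
#' outcome differs from zero. A significant result indicates directional
#' (non-zero-mean) horizontal pleiotropy.
#'
#' @param u_hat Direct-effect estimates (>= 2 values, non-constant).
#' @return A list with `statistic` (t), `df`, and `pvalue`.
#' @export
directional_pleiotropy_test <- function(u_hat) {
  if (length(u_hat) < 2)
    stop("directional pleiotropy test requires at least 2 SNPs")
  if (stats::sd(u_hat) == 0)
    stop("directional pleiotropy test undefined for constant u_hat")
  tt <- stats::t.test(u_hat, mu = 0)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       pvalue = tt$p.value)
}

#' Test for violation of the InSIDE assumption
#'
#' Pearson correlation test of the direct SNP effects on the outcome
#' against the SNP effects on the exposure. A significant correlation
#' `cor(u, b)` indicates that instrument strength is not independent of the
#' direct effects (InSIDE violated), as induced by a genetic confounder.
#'
#' @param u_hat Direct-effect estimates.
#' @param b_hat Exposure-effect estimates (same length, >= 3, both
#'   non-constant).
#' @return A list with `r`, `statistic` (t with `df = m - 2`), `df`, and
#'   `pvalue`.
#' @export
inside_test <- function(u_hat, b_hat) {
  if (length(u_hat) != length(b_hat))
    stop("u_hat and b_hat must have the same length")
  if (length(u_hat) < 3) stop("InSIDE test requires at least 3 SNPs")
  if (stats::sd(u_hat) == 0 || stats::sd(b_hat) == 0)
    stop("InSIDE test undefined for constant input")
  ct <- stats::cor.test(u_hat, b_hat)
  list(r = unname(ct$estimate), statistic = unname(ct$statistic),
       df = unname(ct$parameter), pvalue = ct$p.value)
}

#' Pleiotropy diagnostics for a fitted MR-LOVA model
#'
#' Computes the directional-pleiotropy t-test and the InSIDE-violation
#' correlation test on the direct effects `u_hat` evaluated at the
#' converged `tau_hat` over all instruments in the fit's panel (not only
#' the selected ones -- excluded instruments carry the pleiotropy signal
#' the tests target).
#'
#' @param fit An [mr_lova()] fit.
#' @return An object of class `mr_diagnostics` with fields `dir_pleio_t`,
#'   `dir_pleio_df`, `dir_pleio_p`, `inside_r`, `inside_p`, `n_snps_used`.
#' @export
mr_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "mr_lova"))
  dir <- directional_pleiotropy_test(fit$u_hat)
  ins <- inside_test(fit$u_hat, fit$b_hat)
  structure(list(dir_pleio_t = dir$statistic, dir_pleio_df = dir$df,
                 dir_pleio_p = dir$pvalue,
                 inside_r = ins$r, inside_p = ins$pvalue,
                 n_snps_used = length(fit$u_hat)),
            class = "mr_diagnostics")
}

#' @export
print.mr_diagnostics <- function(x, ...) {
  cat("Pleiotropy diagnostics (", x$n_snps_used, " SNPs)\n", sep = "")
  cat(sprintf("  directional pleiotropy: t = %.3f, df = %d, p = %.3g\n",
              x$dir_pleio_t, x$dir_pleio_df, x$dir_pleio_p))
  cat(sprintf("  InSIDE violation:       r = %.3f, p = %.3g\n",
              x$inside_r, x$inside_p))
  invisible(x)
}

#' Inverse-variance-weighted baseline estimator
#'
#' Fixed-effect IVW: precision-weighted (`se_g^-2`) regression of the
#' outcome effects on the exposure effects through the origin. With a
#' single instrument this reduces to the Wald ratio `g_hat / b_hat`.
#'
#' @param panel A standardized `mr_panel`.
#' @return A list of class `mr_result` with `tau_hat`, `se_tau`, `pvalue`,
#'   `method`.
#' @export
mr_ivw <- function(panel) {
  stopifnot(inherits(panel, "mr_panel"),
            isTRUE(attr(panel, "standardized")))
  if (nrow(panel) < 1) stop("IVW requires at least 1 SNP")
  w <- 1 / panel$se_g^2
  tau <- wls_origin(panel$b_hat, panel$g_hat, w)
  se <- 1 / sqrt(sum(w * panel$b_hat^2))
  structure(list(tau_hat = tau, se_tau = se, pvalue = z_pvalue(tau / se),
                 method = "ivw", m = nrow(panel)),
            class = "mr_result")
}

#' MR-Egger baseline estimator
#'
#' Precision-weighted regression of the outcome effects on the exposure
#' effects with an intercept. The slope estimates the causal effect under
#' InSIDE; a non-zero intercept indicates directional pleiotropy.
#'
#' @param panel A standardized `mr_panel` with at least 3 SNPs.
#' @return A list of class `mr_result` with `tau_hat`, `se_tau`, `pvalue`,
#'   `intercept`, `intercept_se`, `intercept_pvalue`, `method`.
#' @export
mr_egger <- function(panel) {
  stopifnot(inherits(panel, "mr_panel"),
            isTRUE(attr(panel, "standardized")))
  if (nrow(panel) < 3) stop("MR-Egger requires at least 3 SNPs")
  fit <- stats::lm(g_hat ~ b_hat, data = panel, weights = 1 / panel$se_g^2)
  sm <- summary(fit)$coefficients
  structure(list(tau_hat = sm["b_hat", 1], se_tau = sm["b_hat", 2],
                 pvalue = z_pvalue(sm["b_hat", 1] / sm["b_hat", 2]),
                 intercept = sm["(Intercept)", 1],
                 intercept_se = sm["(Intercept)", 2],
                 intercept_pvalue = z_pvalue(sm["(Intercept)", 1] /
                                               sm["(Intercept)", 2]),
                 method = "egger", m = nrow(panel)),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s estimate: tau_hat = %.4f  se = %.4f  p = %.3g (%d SNPs)\n",
              x$method, x$tau_hat, x$se_tau, x$pvalue, x$m))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.4g (se %.4g, p = %.3g)\n",
                x$intercept, x$intercept_se, x$intercept_pvalue))
  invisible(x)
}
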