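# The MR-LOVA stochastic EM engine on summary statistics.
#
# Working scale: standardized effects (per SD of genotype and trait), so
# var(g_hat_j) = se_g_j^2 ~ 1/n_out and the latent-outcome variance is
# var(upsilon) = 1 + tau^2 - 2 tau cov(y, c).

#' Approximate the exposure-outcome phenotypic covariance
#'
#' Under column-standardized genotypes and approximately independent
#' (clumped) SNPs, `cov(y, c)` is approximated by the genetic covariance
#' `sum_j g_hat_j * b_hat_j` over the panel. The value is clipped to
#' `(-0.999, 0.999)` so that the latent-outcome variance
#' `1 + tau^2 - 2 tau cov(y,c)` stays positive for every tau.
#'
#' @param panel A standardized `mr_panel` with at least 2 SNPs.
#' @return A scalar covariance approximation.
#' @export
estimate_cov_yc <- function(panel) {
  stopifnot(inherits(panel, "mr_panel"),
            isTRUE(attr(panel, "standardized")))
  if (nrow(panel) < 2)
    stop("estimate_cov_yc requires at least 2 SNPs")
  cov_yc <- sum(panel$g_hat * panel$b_hat)
  if (abs(cov_yc) >= 0.999) {
    warning("cov(y,c) approximation ", signif(cov_yc, 4),
            " clipped to keep var(upsilon) positive")
    cov_yc <- sign(cov_yc) * 0.999
  }
  cov_yc
}

#' E-step: impute direct SNP effects on the outcome
#'
#' Updates the direct-effect estimates from the latent outcome
#' `upsilon = y - c tau`:
#' `u_hat_j = g_hat_j - tau * b_hat_j` with sampling variance
#' `var(u_hat_j) = var(g_hat_j) + (tau^2 - 2 tau cov(y,c)) / n_out`.
#' At `tau = 0` this is the identity on `(g_hat, var(g_hat))`.
#'
#' @param g_hat,b_hat Standardized outcome and exposure effects.
#' @param se_g Standard errors of `g_hat`.
#' @param tau Current causal-effect estimate.
#' @param cov_yc Covariance approximation from [estimate_cov_yc()].
#' @param n_out Outcome GWAS sample size.
#' @param var_floor Lower bound applied to the variances; default `1e-12`.
#' @return List with `u_hat` and `var_u`.
#' @export
e_step <- function(g_hat, b_hat, se_g, tau, cov_yc, n_out,
                   var_floor = 1e-12) {
  u_hat <- g_hat - tau * b_hat
  var_u <- se_g^2 + (tau^2 - 2 * tau * cov_yc) / n_out
  if (all(var_u <= 0))
    stop("E-step produced no positive variances (tau = ", signif(tau, 6),
         ", cov_yc = ", signif(cov_yc, 6), ")")
  if (any(var_u <= 0))
    warning(sum(var_u <= 0), " direct-effect variance(s) floored at ",
            var_floor)
  list(u_hat = u_hat, var_u = pmax(var_u, var_floor))
}

#' Inclusion indicator for valid instruments
#'
#' A SNP is classified as a valid instrument (`I_j = 1`) when its direct
#' effect on the latent outcome is non-significant (two-sided normal
#' p-value of `u_hat_j / sqrt(var_u_j)` above `p_outcome`; exclusion
#' restriction) and its exposure effect is significant (p-value of
#' `b_hat_j / se_b_j` below `p_exposure`; relevance).
#'
#' @param u_hat,var_u Direct-effect estimates and variances (E-step).
#' @param b_hat,se_b Standardized exposure effects and standard errors.
#' @param p_outcome Latent-outcome p-value threshold; default `0.05`.
#' @param p_exposure Exposure p-value threshold; default `5e-8`.
#' @return A logical inclusion vector.
#' @export
inclusion_indicator <- function(u_hat, var_u, b_hat, se_b,
                                p_outcome = 0.05, p_exposure = 5e-8) {
  p_u <- z_pvalue(u_hat / sqrt(var_u))
  p_b <- z_pvalue(b_hat / se_b)
  p_u > p_outcome & p_b < p_exposure
}

#' M-step: IVW update of the causal effect
#'
#' Inverse-variance-weighted regression through the origin of the imputed
#' direct effects on the exposure effects over the included instruments:
#' \deqn{\Delta\tau = \frac{\sum_j I_j \hat u_j \hat b_j se(\hat u_j)^{-2}}
#'                        {\sum_j I_j \hat b_j^2 se(\hat u_j)^{-2}}.}
#' Because `u_hat` is already residualized on the current `tau`, the value
#' returned is the increment; the caller updates `tau <- tau + m_step_ivw(...)`.
#'
#' @param u_hat,var_u Direct-effect estimates and variances.
#' @param b_hat Standardized exposure effects.
#' @param include Logical (or 0/1) inclusion vector.
#' @return The IVW increment to tau.
#' @export
m_step_ivw <- function(u_hat, var_u, b_hat, include) {
  include <- as.logical(include)
  if (!any(include))
    stop("no valid instruments: empty inclusion set in the M-step")
  wls_origin(b_hat[include], u_hat[include], 1 / var_u[include])
}

# One evaluation of the E-step (+ optional LD adjustment) at a given tau.
.lova_estep <- function(panel, tau, cov_yc, omega, var_floor = 1e-12) {
  es <- e_step(panel$g_hat, panel$b_hat, panel$se_g, tau, cov_yc,
               attr(panel, "n_out"), var_floor)
  if (!is.null(omega)) {
    var_ups <- 1 + tau^2 - 2 * tau * cov_yc
    es <- ld_adjust(es$u_hat, omega, var_ups, attr(panel, "n_out"),
                    var_floor = var_floor)
  }
  es
}

# Core EM loop shared by the observed fit and the permutation refits.
.lova_em <- function(panel, tau0, tol, max_iter, p_outcome, p_exposure,
                     omega, mstep, var_floor = 1e-12, verbose = FALSE) {
  cov_yc <- estimate_cov_yc(panel)
  relevant <- z_pvalue(panel$b_hat / panel$se_b) < p_exposure
  if (!any(relevant))
    stop("no SNPs reach the exposure relevance threshold p < ", p_exposure)

  tau <- tau0
  trace <- data.frame(iteration = 0L, tau = tau0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    es <- .lova_estep(panel, tau, cov_yc, omega, var_floor)
    include <- inclusion_indicator(es$u_hat, es$var_u, panel$b_hat,
                                   panel$se_b, p_outcome, p_exposure)
    if (!any(include)) {
      msg_if(verbose, "iteration ", iter,
             ": empty inclusion set, falling back to relevance-only selection")
      include <- relevant
    }
    delta <- if (mstep == "direct") {
      wls_origin(panel$b_hat[include], panel$g_hat[include],
                 1 / es$var_u[include]) - tau
    } else {
      m_step_ivw(es$u_hat, es$var_u, panel$b_hat, include)
    }
    tau <- tau + delta
    trace <- rbind(trace, data.frame(iteration = iter, tau = tau))
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }

  es <- .lova_estep(panel, tau, cov_yc, omega, var_floor)
  include <- inclusion_indicator(es$u_hat, es$var_u, panel$b_hat,
                                 panel$se_b, p_outcome, p_exposure)
  if (!any(include))
    stop("no valid instruments at convergence (tau = ", signif(tau, 6), ")")
  se_tau <- 1 / sqrt(sum(panel$b_hat[include]^2 / es$var_u[include]))
  list(tau_hat = tau, se_tau = se_tau,
       pvalue = z_pvalue(tau / se_tau),
       n_iter = iter, converged = converged,
       include = include, u_hat = es$u_hat, var_u = es$var_u,
       cov_yc = cov_yc, trace = trace)
}

#' Fit MR-LOVA on a summary-statistics panel
#'
#' Runs the stochastic EM algorithm: impute direct SNP effects from the
#' latent outcome at the current `tau` (E-step; LD-adjusted via
#' [ld_adjust()] when `ld` is supplied), classify instruments with
#' [inclusion_indicator()], update `tau` by the IVW increment
#' ([m_step_ivw()]), and iterate to convergence (`|delta tau| < tol`).
#' The standard error at convergence is
#' `se(tau) = (sum_j I_j b_hat_j^2 / var(u_hat_j))^(-1/2)` and the p-value
#' uses the normal reference. If the inclusion set is empty mid-iteration
#' the update falls back to relevance-only selection with a message; an
#' empty set at convergence is an error.
#'
#' @param panel A standardized `mr_panel` (typically after
#'   [relevance_filter()]).
#' @param tau0 Initial causal-effect value. Default 0 (no causal effect),
#'   which guards against convergence to spurious solutions.
#' @param tol Convergence tolerance on the tau increment; default `1e-6`.
#' @param max_iter Maximum EM iterations; default 100. Non-convergence is
#'   flagged (`converged = FALSE`), not an error.
#' @param p_outcome,p_exposure Inclusion thresholds; see
#'   [inclusion_indicator()].
#' @param ld Optional `mr_ld` object ([read_ld_matrix()]) for the
#'   reference-panel LD-adjusted path.
#' @param n_perm Number of permutations for an empirical p-value on tau
#'   (0 = skip); see [permutation_test()].
#' @param seed Seed for the permutation test.
#' @param mstep `"increment"` (default) regresses the residualized `u_hat`
#'   on `b_hat` and updates additively, making the true value a fixed
#'   point; `"direct"` regresses `g_hat` on `b_hat` with the current
#'   `var(u_hat)` weights (sensitivity analysis).
#' @param verbose Emit iteration messages.
#'
#' @return An object of class `mr_lova`: `tau_hat`, `se_tau`, `pvalue`,
#'   `n_iter`, `converged`, `n_selected`, `selected_ids`, `include`,
#'   `u_hat`, `var_u`, `trace` (tau per iteration), `perm_pvalue` (or `NA`),
#'   and the fit parameters in `params`.
#' @export
#' @examples
#' set.seed(1)
#' m <- 50; n <- 1e4
#' b <- runif(m, 0.05, 0.1)
#' panel <- mr_panel(paste0("rs", 1:m),
#'                   b_hat = b + rnorm(m, 0, 1 / sqrt(n)),
#'                   se_b = rep(1 / sqrt(n), m),
#'                   g_hat = 0.2 * b + rnorm(m, 0, 1 / sqrt(n)),
#'                   se_g = rep(1 / sqrt(n), m),
#'                   n_exp = n, n_out = n)
#' fit <- mr_lova(panel)
#' fit
mr_lova <- function(panel, tau0 = 0, tol = 1e-6, max_iter = 100L,
                    p_outcome = 0.05, p_exposure = 5e-8, ld = NULL,
                    n_perm = 0L, seed = NULL,
                    mstep = c("increment", "direct"), verbose = FALSE) {
  stopifnot(inherits(panel, "mr_panel"),
            isTRUE(attr(panel, "standardized")))
  mstep <- match.arg(mstep)
  omega <- if (!is.null(ld)) align_ld(ld, panel$snp) else NULL

  em <- .lova_em(panel, tau0, tol, max_iter, p_outcome, p_exposure,
                 omega, mstep, verbose = verbose)
  res <- structure(
    c(em,
      list(n_selected = sum(em$include),
           selected_ids = panel$snp[em$include],
           snp = panel$snp,
           b_hat = panel$b_hat, se_b = panel$se_b,
           g_hat = panel$g_hat, se_g = panel$se_g,
           m = nrow(panel),
           n_exp = attr(panel, "n_exp"), n_out = attr(panel, "n_out"),
           method = if (is.null(ld)) "mr_lova" else "mr_lova_ref",
           perm_pvalue = NA_real_,
           params = list(tau0 = tau0, tol = tol, max_iter = max_iter,
                         p_outcome = p_outcome, p_exposure = p_exposure,
                         mstep = mstep, ld = ld, seed = seed))),
    class = "mr_lova")
  if (n_perm > 0)
    res$perm_pvalue <- permutation_test(panel, res, n_perm = n_perm,
                                        seed = seed)
  res
}

#' @export
print.mr_lova <- function(x, ...) {
  cat("MR-LOVA causal-effect estimate (", x$method, ")\n", sep = "")
  cat(sprintf("  tau_hat = %.4f  se = %.4f  p = %.3g\n",
              x$tau_hat, x$se_tau, x$pvalue))
  if (!is.na(x$perm_pvalue))
    cat(sprintf("  permutation p = %.3g\n", x$perm_pvalue))
  cat(sprintf("  instruments: %d selected of %d (converged: %s, %d iterations)\n",
              x$n_selected, x$m, x$converged, x$n_iter))
  invisible(x)
}
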