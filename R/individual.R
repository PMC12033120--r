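# Individual-level-data path of the MR-LOVA estimator.

#' Construct an individual-level cohort
#'
#' Bundles a genotype dosage matrix with the phenotypes measured in that
#' cohort. Constant-genotype columns cannot serve as instruments and are
#' dropped with a warning.
#'
#' @param X `n x m` genotype dosage matrix with entries 0/1/2.
#' @param exposure Optional exposure phenotype vector (length `n`).
#' @param outcome Optional outcome phenotype vector (length `n`).
#' @param snp_ids SNP identifiers; defaults to `colnames(X)` or
#'   `snp1..snpm`.
#' @return An object of class `mr_cohort` with elements `X`, `c`, `y`,
#'   `snp_ids`.
#' @export
cohort_data <- function(X, exposure = NULL, outcome = NULL, snp_ids = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(X < 0 | X > 2))
    stop("genotype dosages must lie in [0, 2]")
  if (is.null(snp_ids)) snp_ids <- colnames(X) %||% paste0("snp", seq_len(ncol(X)))
  if (!is.null(exposure) && length(exposure) != nrow(X))
    stop("exposure length does not match the number of individuals")
  if (!is.null(outcome) && length(outcome) != nrow(X))
    stop("outcome length does not match the number of individuals")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant-genotype SNP(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
    snp_ids <- snp_ids[sds > 0]
  }
  structure(list(X = X, c = exposure, y = outcome,
                 snp_ids = as.character(snp_ids)),
            class = "mr_cohort")
}

# Column-standardize a dosage matrix (mean 0, SD 1).
std_genotypes <- function(X) {
  mu <- colMeans(X)
  sds <- sqrt(colMeans(X^2) - mu^2) * sqrt(nrow(X) / (nrow(X) - 1))
  sweep(sweep(X, 2, mu, "-"), 2, sds, "/")
}

# Per-SNP simple linear regression of trait t on each standardized SNP.
# Returns effects on the standardized-genotype scale with their SEs.
# t is used as given (callers standardize the trait where appropriate).
snp_regression <- function(Xs, t) {
  n <- nrow(Xs)
  tc <- t - mean(t)
  beta <- drop(crossprod(Xs, tc)) / (n - 1)
  resvar <- pmax(stats::var(t) - beta^2, 0)
  se <- sqrt(resvar / (n - 2))
  list(beta = beta, se = pmax(se, .Machine$double.eps))
}

#' Fit MR-LOVA on individual-level cohorts
#'
#' The individual-level analogue of [mr_lova()]. Exposure SNP effects
#' `b_hat` come from per-SNP regressions of the standardized exposure on
#' standardized dosages in the exposure cohort. Each EM iteration forms the
#' latent outcome `upsilon = y - c_pred * tau` in the outcome cohort --
#' where `c_pred` is the genetic prediction `X b_hat` in the two-sample
#' case, or the observed exposure when `one_sample = TRUE` -- regresses
#' `upsilon` on each SNP to obtain `u_hat_j` and `se(u_hat_j)`, and then
#' proceeds exactly as the summary-level fit (inclusion indicator, IVW
#' increment, convergence on `|delta tau| < tol`).
#'
#' @param exposure_cohort `mr_cohort` with the exposure phenotype.
#' @param outcome_cohort `mr_cohort` with the outcome phenotype (disjoint
#'   individuals in the two-sample design; the same cohort with both
#'   phenotypes for `one_sample = TRUE`).
#' @param one_sample Use the observed exposure in the outcome cohort
#'   instead of its genetic prediction. Default `FALSE`.
#' @inheritParams mr_lova
#' @return An object of class `mr_lova` (method `"mr_lova_ind"`).
#' @export
mr_lova_individual <- function(exposure_cohort, outcome_cohort,
                               one_sample = FALSE, tau0 = 0, tol = 1e-6,
                               max_iter = 100L, p_outcome = 0.05,
                               p_exposure = 5e-8, verbose = FALSE) {
  stopifnot(inherits(exposure_cohort, "mr_cohort"),
            inherits(outcome_cohort, "mr_cohort"))
  if (is.null(exposure_cohort$c))
    stop("exposure cohort lacks an exposure phenotype")
  if (is.null(outcome_cohort$y))
    stop("outcome cohort lacks an outcome phenotype")
  shared <- intersect(exposure_cohort$snp_ids, outcome_cohort$snp_ids)
  if (length(shared) < 2) stop("cohorts share fewer than 2 instruments")

  X1 <- exposure_cohort$X[, match(shared, exposure_cohort$snp_ids),
                          drop = FALSE]
  X2 <- outcome_cohort$X[, match(shared, outcome_cohort$snp_ids),
                         drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  c1 <- drop(scale(exposure_cohort$c))
  y2 <- drop(scale(outcome_cohort$y))
  X1s <- std_genotypes(X1)
  X2s <- std_genotypes(X2)

  bg <- snp_regression(X1s, c1)
  b_hat <- bg$beta; se_b <- bg$se
  relevant <- z_pvalue(b_hat / se_b) < p_exposure
  if (!any(relevant))
    stop("no SNPs reach the exposure relevance threshold p < ", p_exposure)

  c_pred <- if (one_sample) {
    if (is.null(outcome_cohort$c))
      stop("one_sample = TRUE requires the exposure in the outcome cohort")
    drop(scale(outcome_cohort$c))
  } else {
    drop(X2s %*% b_hat)
  }

  # upsilon = y - c_pred * tau is linear in tau, so the per-SNP regression
  # coefficients and the variance pieces can be precomputed once.
  cxy <- drop(crossprod(X2s, y2 - mean(y2))) / (n2 - 1)
  cxc <- drop(crossprod(X2s, c_pred - mean(c_pred))) / (n2 - 1)
  v_y <- stats::var(y2); v_c <- stats::var(c_pred)
  cov_yc_ph <- stats::cov(y2, c_pred)

  u_at <- function(tau) {
    u_hat <- cxy - tau * cxc
    var_ups <- v_y + tau^2 * v_c - 2 * tau * cov_yc_ph
    se2 <- pmax(var_ups - u_hat^2, 0) / (n2 - 2)
    list(u_hat = u_hat, var_u = pmax(se2, 1e-12))
  }

  tau <- tau0
  trace <- data.frame(iteration = 0L, tau = tau0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    es <- u_at(tau)
    include <- inclusion_indicator(es$u_hat, es$var_u, b_hat, se_b,
                                   p_outcome, p_exposure)
    if (!any(include)) {
      msg_if(verbose, "iteration ", iter,
             ": empty inclusion set, falling back to relevance-only selection")
      include <- relevant
    }
    delta <- m_step_ivw(es$u_hat, es$var_u, b_hat, include)
    tau <- tau + delta
    trace <- rbind(trace, data.frame(iteration = iter, tau = tau))
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }

  es <- u_at(tau)
  include <- inclusion_indicator(es$u_hat, es$var_u, b_hat, se_b,
                                 p_outcome, p_exposure)
  if (!any(include))
    stop("no valid instruments at convergence (tau = ", signif(tau, 6), ")")
  se_tau <- 1 / sqrt(sum(b_hat[include]^2 / es$var_u[include]))

  structure(list(tau_hat = tau, se_tau = se_tau,
                 pvalue = z_pvalue(tau / se_tau),
                 n_iter = iter, converged = converged,
                 include = include, u_hat = es$u_hat, var_u = es$var_u,
                 trace = trace,
                 n_selected = sum(include), selected_ids = shared[include],
                 snp = shared, b_hat = b_hat, se_b = se_b,
                 g_hat = cxy, se_g = sqrt(pmax(v_y - cxy^2, 0) / (n2 - 2)),
                 m = length(shared), n_exp = n1, n_out = n2,
                 method = "mr_lova_ind", perm_pvalue = NA_real_,
                 params = list(tau0 = tau0, tol = tol, max_iter = max_iter,
                               p_outcome = p_outcome,
                               p_exposure = p_exposure,
                               one_sample = one_sample)),
            class = "mr_lova")
}
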