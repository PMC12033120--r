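# Internal helpers shared across modules.

# Two-sided p-value from a z statistic (normal reference; GWAS n is large,
# so the t correction is negligible and the normal is used throughout).
z_pvalue <- function(z) 2 * stats::pnorm(-abs(z))

# Weighted regression through the origin of y on x with weights w:
# slope = sum(w x y) / sum(w x^2). Core IVW algebra used by the M-step and
# the IVW baseline; oracle-tested against lm() normal equations.
wls_origin <- function(x, y, w) {
  denom <- sum(w * x^2)
  if (denom <= 0) stop("weighted least squares: zero denominator")
  sum(w * x * y) / denom
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg_if <- function(verbose, ...) if (isTRUE(verbose)) message(...)
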