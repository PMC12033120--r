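# Reading, harmonizing, standardizing and filtering GWAS summary statistics.

.default_columns <- c(snp = "SNP", effect_allele = "A1", other_allele = "A2",
                      beta = "BETA", se = "SE", pvalue = "P", n = "N")

#' Read a GWAS summary-statistics table
#'
#' Reads a whitespace- or TAB-delimited summary-statistics file into a
#' validated table with one row per SNP. Rows with missing or non-numeric
#' effect size or standard error are dropped with a warning; duplicated SNP
#' identifiers and rows whose two alleles are identical are likewise dropped.
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Named character vector mapping the internal field names
#'   `snp`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `n` to
#'   the column names used in the file. Defaults to
#'   `SNP, A1, A2, BETA, SE, P, N`. `pvalue` and `n` entries are optional;
#'   p-values are recomputable from `beta`/`se` and `n` may instead be
#'   supplied via the `n` argument.
#' @param n Optional global sample size, used when the file has no
#'   per-SNP sample-size column.
#' @param verbose Emit messages about dropped rows.
#'
#' @return A `data.frame` of class `mr_sumstats` with columns
#'   `snp`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `n`.
#' @export
read_summary_stats <- function(path, column_map = NULL, n = NULL,
                               verbose = TRUE) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  map <- .default_columns
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(map))
    if (length(bad)) stop("unknown column_map fields: ",
                          paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- map[mandatory][!map[mandatory] %in% names(dt)]
  if (length(missing_cols))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    snp = as.character(dt[[map["snp"]]]),
    effect_allele = toupper(as.character(dt[[map["effect_allele"]]])),
    other_allele = toupper(as.character(dt[[map["other_allele"]]])),
    beta = suppressWarnings(as.numeric(dt[[map["beta"]]])),
    se = suppressWarnings(as.numeric(dt[[map["se"]]])),
    stringsAsFactors = FALSE
  )
  out$pvalue <- if (map["pvalue"] %in% names(dt))
    suppressWarnings(as.numeric(dt[[map["pvalue"]]])) else NA_real_
  out$n <- if (map["n"] %in% names(dt))
    suppressWarnings(as.numeric(dt[[map["n"]]])) else n %||% NA_real_
  as_mr_sumstats(out, source = path, verbose = verbose)
}

# Validate a raw summary table: drop unusable rows, enforce invariants.
as_mr_sumstats <- function(out, source = "summary table", verbose = TRUE) {
  bad_beta <- !is.finite(out$beta) | !is.finite(out$se)
  if (any(bad_beta)) {
    warning(sum(bad_beta), " row(s) with missing/non-numeric beta or se ",
            "dropped from ", source)
    out <- out[!bad_beta, , drop = FALSE]
  }
  bad_se <- out$se <= 0
  if (any(bad_se)) {
    warning(sum(bad_se), " row(s) with non-positive se dropped from ", source)
    out <- out[!bad_se, , drop = FALSE]
  }
  same_allele <- out$effect_allele == out$other_allele
  if (any(same_allele)) {
    warning(sum(same_allele), " row(s) with identical alleles dropped from ",
            source)
    out <- out[!same_allele, , drop = FALSE]
  }
  dup <- duplicated(out$snp)
  if (any(dup)) {
    warning(sum(dup), " duplicated SNP id(s) dropped from ", source)
    out <- out[!dup, , drop = FALSE]
  }
  if (!nrow(out)) stop("no usable rows in ", source)
  msg_if(verbose, nrow(out), " SNPs read from ", source)
  rownames(out) <- NULL
  class(out) <- c("mr_sumstats", "data.frame")
  out
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two summary tables on shared SNP identifiers and a shared effect
#' allele. When the outcome table codes effect/other alleles in the opposite
#' orientation to the exposure table, the outcome effect sign is flipped;
#' SNPs whose allele pairs do not match are dropped. Palindromic (A/T, C/G)
#' SNPs, whose strand cannot be resolved from alleles alone, are optionally
#' dropped.
#'
#' @param exposure,outcome `mr_sumstats` tables (see [read_summary_stats()]).
#' @param drop_palindromic Drop A/T and C/G SNPs. Default `FALSE`.
#' @param verbose Emit per-action counts.
#'
#' @return A `data.frame` of class `mr_panel` (not yet standardized) with
#'   columns `snp`, `effect_allele`, `other_allele`, `beta_exp`, `se_exp`,
#'   `n_exp`, `beta_out`, `se_out`, `n_out`.
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = FALSE,
                      verbose = TRUE) {
  if (!nrow(exposure) || !nrow(outcome))
    stop("harmonization requires non-empty exposure and outcome tables")
  shared <- intersect(exposure$snp, outcome$snp)
  if (!length(shared))
    stop("harmonization failed: no shared SNPs between exposure and outcome")
  ex <- exposure[match(shared, exposure$snp), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp), , drop = FALSE]

  same <- ex$effect_allele == ou$effect_allele &
    ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele &
    ex$other_allele == ou$effect_allele
  keep <- same | swapped
  beta_out <- ifelse(swapped, -ou$beta, ou$beta)

  palindromic <- (ex$effect_allele == "A" & ex$other_allele == "T") |
    (ex$effect_allele == "T" & ex$other_allele == "A") |
    (ex$effect_allele == "C" & ex$other_allele == "G") |
    (ex$effect_allele == "G" & ex$other_allele == "C")
  if (drop_palindromic) keep <- keep & !palindromic

  msg_if(verbose, length(shared), " shared SNPs; ",
         sum(swapped & keep), " outcome effect(s) flipped to the exposure ",
         "effect allele; ", sum(!(same | swapped)),
         " allele-mismatched SNP(s) dropped",
         if (drop_palindromic)
           paste0("; ", sum(palindromic & (same | swapped)),
                  " palindromic SNP(s) dropped") else "")
  if (!any(keep))
    stop("harmonization failed: no SNPs remain after allele matching")

  panel <- data.frame(
    snp = ex$snp[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_exp = ex$beta[keep], se_exp = ex$se[keep], n_exp = ex$n[keep],
    beta_out = beta_out[keep], se_out = ou$se[keep], n_out = ou$n[keep],
    stringsAsFactors = FALSE
  )
  rownames(panel) <- NULL
  class(panel) <- c("mr_panel", "data.frame")
  attr(panel, "standardized") <- FALSE
  panel
}

#' Standardize GWAS effect estimates
#'
#' Converts effect estimates to the standardized scale (per SD of genotype
#' and trait) via `z / sqrt(n)` with `z = beta / se`; the standardized
#' standard error is `1 / sqrt(n)` (sampling variance `1/n`). The `z^2/n`
#' correction is ignored because the per-SNP variance explained is close to
#' zero for typical instruments, so `var(g_hat) = 1/n` holds to first order.
#'
#' @param beta,se Effect estimates and standard errors (any consistent scale).
#' @param n Sample size(s), `> 1`.
#'
#' @return A list with standardized `beta` and `se` vectors.
#' @export
standardize_effects <- function(beta, se, n) {
  if (any(!is.finite(n)) || any(n <= 1))
    stop("standardization requires sample sizes n > 1")
  if (any(se <= 0)) stop("standardization requires positive standard errors")
  list(beta = (beta / se) / sqrt(n), se = 1 / sqrt(n))
}

#' Standardize a harmonized panel
#'
#' Applies [standardize_effects()] to both sides of a harmonized panel,
#' producing the standardized exposure effects `b_hat` (se `se_b`) and
#' outcome effects `g_hat` (se `se_g`) the EM engine works on.
#'
#' @param panel An `mr_panel` from [harmonize()].
#' @return The panel with columns `b_hat`, `se_b`, `g_hat`, `se_g` added,
#'   attribute `standardized = TRUE`, and scalar attributes `n_exp`, `n_out`
#'   (median per-SNP sample sizes).
#' @export
standardize_panel <- function(panel) {
  stopifnot(inherits(panel, "mr_panel"))
  if (isTRUE(attr(panel, "standardized"))) return(panel)
  ex <- standardize_effects(panel$beta_exp, panel$se_exp, panel$n_exp)
  ou <- standardize_effects(panel$beta_out, panel$se_out, panel$n_out)
  panel$b_hat <- ex$beta
  panel$se_b <- ex$se
  panel$g_hat <- ou$beta
  panel$se_g <- ou$se
  attr(panel, "standardized") <- TRUE
  attr(panel, "n_exp") <- stats::median(panel$n_exp)
  attr(panel, "n_out") <- stats::median(panel$n_out)
  panel
}

#' Construct a standardized panel directly
#'
#' Convenience constructor for a standardized harmonized panel from vectors
#' already on the standardized scale (used by the simulator and in tests).
#'
#' @param snp SNP identifiers.
#' @param b_hat,se_b Standardized exposure effects and standard errors.
#' @param g_hat,se_g Standardized outcome effects and standard errors.
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes.
#' @return A standardized `mr_panel`.
#' @export
mr_panel <- function(snp, b_hat, se_b, g_hat, se_g, n_exp, n_out) {
  m <- length(snp)
  b_hat <- rep_len(b_hat, m); se_b <- rep_len(se_b, m)
  g_hat <- rep_len(g_hat, m); se_g <- rep_len(se_g, m)
  stopifnot(all(se_b > 0), all(se_g > 0), !anyDuplicated(snp))
  panel <- data.frame(snp = as.character(snp),
                      b_hat = b_hat, se_b = se_b,
                      g_hat = g_hat, se_g = se_g,
                      n_exp = n_exp, n_out = n_out,
                      stringsAsFactors = FALSE)
  class(panel) <- c("mr_panel", "data.frame")
  attr(panel, "standardized") <- TRUE
  attr(panel, "n_exp") <- stats::median(n_exp)
  attr(panel, "n_out") <- stats::median(n_out)
  panel
}

#' Filter instruments on the relevance assumption
#'
#' Retains SNPs whose two-sided exposure p-value (normal reference on
#' `z = b_hat / se_b`) is below `p_exposure`, the genome-wide significance
#' threshold by default. Order is preserved.
#'
#' @param panel A standardized `mr_panel`.
#' @param p_exposure Exposure p-value threshold; default `5e-8`.
#' @param verbose Emit the retained count.
#' @return The filtered panel.
#' @export
relevance_filter <- function(panel, p_exposure = 5e-8, verbose = TRUE) {
  stopifnot(inherits(panel, "mr_panel"),
            isTRUE(attr(panel, "standardized")))
  if (!nrow(panel)) stop("relevance_filter: empty panel")
  p <- z_pvalue(panel$b_hat / panel$se_b)
  keep <- p < p_exposure
  if (!any(keep))
    stop("no SNPs reach the exposure relevance threshold p < ", p_exposure)
  msg_if(verbose, sum(keep), "/", nrow(panel),
         " SNPs pass the exposure relevance threshold p < ", p_exposure)
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("standardized", "n_exp", "n_out"))
    attr(out, a) <- attr(panel, a)
  class(out) <- class(panel)
  out
}

#' Write a panel to a TSV file for audit
#'
#' @param panel An `mr_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
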