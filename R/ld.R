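# Reference-panel LD adjustment of the imputed direct effects.

#' Construct an LD correlation matrix object
#'
#' Validates an instrument-by-instrument correlation matrix: symmetry
#' (enforced by averaging with its transpose), unit diagonal, entries in
#' `[-1, 1]`. When the smallest eigenvalue falls below `1e-6` a ridge of
#' `1e-3` is added to the diagonal (logged) so the matrix is invertible.
#'
#' @param omega Square numeric correlation matrix.
#' @param snp_ids SNP identifiers in matrix order.
#' @return An object of class `mr_ld` with elements `omega` and `snp_ids`.
#' @export
ld_matrix <- function(omega, snp_ids) {
  omega <- as.matrix(omega)
  if (nrow(omega) != ncol(omega)) stop("LD matrix must be square")
  if (length(snp_ids) != nrow(omega))
    stop("LD matrix dimension does not match the number of SNP ids")
  if (any(!is.finite(omega))) stop("LD matrix contains non-finite entries")
  if (any(abs(omega) > 1 + 1e-8))
    stop("LD matrix entries must lie in [-1, 1]")
  omega <- (omega + t(omega)) / 2
  if (any(abs(diag(omega) - 1) > 1e-6))
    stop("LD matrix must have unit diagonal")
  diag(omega) <- 1
  ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-6) {
    message("LD matrix smallest eigenvalue ", signif(ev_min, 3),
            " < 1e-6; adding ridge 1e-3 to the diagonal")
    omega <- omega + diag(1e-3, nrow(omega))
  }
  structure(list(omega = omega, snp_ids = as.character(snp_ids)),
            class = "mr_ld")
}

#' Read an LD matrix from plain-text files
#'
#' Reads a whitespace-delimited square correlation matrix (plink `.ld`
#' compatible ordering) and a sidecar file listing one SNP id per line in
#' the same order.
#'
#' @param matrix_path Path to the square matrix file (no header).
#' @param snp_path Path to the SNP-id list.
#' @return An `mr_ld` object (see [ld_matrix()]).
#' @export
read_ld_matrix <- function(matrix_path, snp_path) {
  omega <- as.matrix(data.table::fread(matrix_path, header = FALSE,
                                       data.table = FALSE))
  dimnames(omega) <- NULL
  snp_ids <- scan(snp_path, what = character(), quiet = TRUE)
  ld_matrix(omega, snp_ids)
}

# Reorder omega to the panel's SNP order; error on any mismatch.
align_ld <- function(ld, snp) {
  stopifnot(inherits(ld, "mr_ld"))
  idx <- match(snp, ld$snp_ids)
  if (anyNA(idx))
    stop("LD matrix is missing ", sum(is.na(idx)), " panel SNP(s): ",
         paste(utils::head(snp[is.na(idx)], 5), collapse = ", "))
  ld$omega[idx, idx, drop = FALSE]
}

#' LD-adjust imputed direct effects
#'
#' Converts the marginal direct-effect estimates into joint (multiple
#' regression) estimates using the instrument correlation matrix:
#' `u_adj = solve(Omega) %*% u_hat`, with variances
#' `var(u_adj)_j = [(n Omega)^-1]_jj * (var(upsilon) - R^2)` where
#' `R^2 = u_adj' Omega u_adj = u_hat' solve(Omega) u_hat` is the variance
#' of the latent outcome explained jointly by the instruments. `R^2` is
#' capped below `var(upsilon)` with a warning.
#'
#' @param u_hat Marginal direct-effect estimates (standardized scale).
#' @param omega Correlation matrix aligned to `u_hat` (plain matrix or
#'   `mr_ld`).
#' @param var_upsilon Latent-outcome variance `1 + tau^2 - 2 tau cov(y,c)`.
#' @param n_out Outcome GWAS sample size.
#' @param var_floor Lower bound on the adjusted variances.
#' @return List with adjusted `u_hat` and `var_u`.
#' @export
ld_adjust <- function(u_hat, omega, var_upsilon, n_out, var_floor = 1e-12) {
  if (inherits(omega, "mr_ld")) omega <- omega$omega
  m <- length(u_hat)
  if (!is.matrix(omega) || nrow(omega) != m || ncol(omega) != m)
    stop("LD matrix dimensions do not match the number of instruments")
  ch <- tryCatch(chol(omega),
                 error = function(e) stop("LD matrix is singular: ",
                                          conditionMessage(e)))
  omega_inv <- chol2inv(ch)
  u_adj <- drop(omega_inv %*% u_hat)
  r2 <- sum(u_hat * u_adj)
  if (r2 >= var_upsilon) {
    warning("instrument R^2 (", signif(r2, 4), ") >= var(upsilon) (",
            signif(var_upsilon, 4), "); capped")
    r2 <- var_upsilon * (1 - 1e-6)
  }
  var_u <- pmax(diag(omega_inv) / n_out * (var_upsilon - r2), var_floor)
  list(u_hat = u_adj, var_u = var_u)
}
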