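# Fixture builders shared across test files. All fixtures are generated in
# code under seeds set by the individual tests.

# Standardized two-sample panel built directly on the summary scale:
# b_hat ~ N(b_std, 1/n), g_hat ~ N(g_std, 1/n), se = 1/sqrt(n).
make_panel <- function(m, n, b_std, g_std, noise = TRUE) {
  b_std <- rep_len(b_std, m)
  g_std <- rep_len(g_std, m)
  b_hat <- b_std + if (noise) rnorm(m, 0, 1 / sqrt(n)) else 0
  g_hat <- g_std + if (noise) rnorm(m, 0, 1 / sqrt(n)) else 0
  mr_panel(paste0("rs", seq_len(m)), b_hat, rep(1 / sqrt(n), m),
           g_hat, rep(1 / sqrt(n), m), n_exp = n, n_out = n)
}

# Write a summary-statistics file in the default column dialect.
write_sumstats <- function(path, snp, beta, se, n,
                           a1 = "A", a2 = "G", p = NULL) {
  d <- data.frame(SNP = snp, A1 = rep_len(a1, length(snp)),
                  A2 = rep_len(a2, length(snp)), BETA = beta, SE = se,
                  P = if (is.null(p)) 2 * pnorm(-abs(beta / se)) else p,
                  N = rep_len(n, length(snp)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
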