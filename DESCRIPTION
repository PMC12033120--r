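Package: mrlova
Title: Mendelian Randomization via a Latent Outcome Variable and Stochastic EM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomization from GWAS summary statistics
    using a latent outcome variable purged of vertical-pleiotropy effects. A
    stochastic expectation-maximization algorithm alternately imputes direct
    SNP effects on the outcome, selects valid instruments by significance
    criteria on the exposure and the latent outcome, and updates the causal
    effect by inverse-variance-weighted estimation. Includes an LD-adjusted
    path using a reference-panel correlation matrix, an individual-level-data
    path, a permutation test for the causal estimate, statistical tests for
    directional pleiotropy and violation of the InSIDE assumption, IVW and
    MR-Egger baselines, a simulation framework covering four pleiotropy
    scenarios, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
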