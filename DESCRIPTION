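Package: tsmr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) with binary
    exposures and outcomes using GWAS summary statistics: dialect-tolerant
    reading and writing of summary-statistic tables and pairwise LD
    information; greedy p-value-ranked LD clumping, proxy substitution and
    allele harmonization with palindromic-variant handling; inverse-variance
    weighted, MR-Egger, weighted-median and weighted-mode causal estimators;
    heterogeneity and pleiotropy diagnostics (Cochran Q, Egger intercept,
    MR-PRESSO global/outlier/distortion tests, leave-one-out); mRnd-style
    binary-outcome power and smallest-detectable-odds-ratio calculations; a
    synthetic two-sample GWAS generator with known ground truth; and a
    config-driven pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
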