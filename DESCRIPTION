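Package: smcpgwas
Title: Smoothed Minimax Concave Penalized Regression for Genome-Wide
    Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Penalized marginal regression for genome-wide association
    studies that combines the minimax concave penalty (MCP) with a
    linkage-disequilibrium weighted quadratic penalty on differences of
    absolute genetic effects at adjacent SNPs (the SMCP method). Models
    are fitted by coordinate descent over a tuning-parameter path, the
    tuning level is selected by the extended Bayesian information
    criterion (EBIC), and selected SNPs receive leave-one-out p-values.
    Includes a LASSO comparator, single-SNP regression with
    Benjamini-Hochberg correction, readers for VCF, PLINK text, and TSV
    genotypes, and a genotype/trait simulator with controllable
    adjacent-SNP linkage disequilibrium.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
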