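Package: mrclustmed
Title: Clustered Mendelian Randomisation with Two-Step Protein Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting heterogeneous exposure-outcome
    relationships with Mendelian randomisation (MR). Per-variant Wald
    ratios are soft-clustered by an expectation-maximisation mixture model
    with explicit null and junk components, and each cluster receives its
    own inverse-variance weighted MR estimate. A second stage screens a
    molecular (protein) panel for mediators of the cluster-specific
    effects by two-step MR, with product-of-coefficients mediation
    estimates, delta-method standard errors, Monte Carlo confidence
    intervals and between-cluster contrast tests. Includes GWAS
    summary-statistics harmonisation, greedy LD clumping, Steiger
    directionality filtering, weighted allele scores for one-sample MR on
    individual-level data, and a synthetic-data generator that emulates
    the full study design for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
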