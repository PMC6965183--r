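Package: baselinebias
Title: Baseline-Adjustment Bias in Pharmacogenomic Studies of Quantitative Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantifying the false-positive
    bias introduced by adjusting quantitative drug-response phenotypes for the
    baseline measurement, using statin-induced LDL-C lowering as the case study.
    Generates synthetic EHR-like statin cohorts with genotypes, applies new-user
    eligibility filters and baseline/on-treatment measurement-pair selection,
    constructs covariate-residualized (optionally rank-normalized) response and
    level phenotypes, runs per-group single-variant association scans with
    genomic-control diagnostics, combines groups by inverse-variance fixed-effects
    meta-analysis with Cochran's Q and I-squared, performs the baseline versus
    on-treatment heterogeneity (gene-drug interaction) test, calls independent
    loci, and provides closed-form large-sample expectations for the genotype
    coefficient of each phenotype definition under the Gaussian measurement-error
    model (the regression-toward-the-mean bias mechanism).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    jsonlite
Config/testthat/edition: 3
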