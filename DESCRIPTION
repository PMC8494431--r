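Package: rohburden
Title: Runs of Homozygosity, Genomic Inbreeding and Case-Control Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in hard-call SNP genotype data
    with a two-step sliding-window caller, summarises per-sample homozygosity
    burden as the fraction of the autosome in ROH (FROH) and as the
    correlation-between-uniting-gametes inbreeding coefficient (F3), tests
    burden and 500-kb regional ROH exposure against case-control status with
    covariate-adjusted logistic regression, and combines estimates across
    studies by DerSimonian-Laird random-effects or inverse-variance
    fixed-effects meta-analysis. Includes PLINK-dialect text and binary
    genotype readers and writers, pre-analysis quality-control filters, a
    synthetic case-control cohort generator with planted autozygous segments
    for ground-truth validation, and a config-driven pipeline layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
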