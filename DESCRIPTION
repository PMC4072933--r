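Package: methfam
Title: Family-Based Variance-Component Analysis of DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimation of the genetic heritability of DNA methylation from
    twin-family cohorts. Provides a synthetic twin-family data generator
    (pedigrees, gene-dropped genotypes, beta-value methylation matrices with
    known variance components), probe quality-control filters and per-probe
    logistic-link normalisation, intraclass correlations for relative pairs,
    per-probe maximum-likelihood variance-component estimation (additive
    genetic and nuclear-family common environment) with boundary-aware
    likelihood-ratio tests and false-discovery-rate control, reference-based
    blood cell-composition estimation, and family-aware mQTL association
    scans.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
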