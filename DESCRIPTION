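Package: polyfrs
Title: Polygenic Analysis of the Framingham Risk Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Three-arm polygenic analysis of a Framingham-style
    cardiovascular risk score: sex-specific risk-score phenotype
    construction from published regression coefficients, genome-wide
    association with two-tier quality control and principal-component
    stratification adjustment, ten-fold cross-validated p-value-binned
    polygenic risk scoring, and SNP-heritability estimation via an
    allele-frequency-weighted genetic relationship matrix with three
    REML algorithms (average information, Fisher scoring,
    expectation-maximization) and pair-filtered Haseman-Elston
    regression with subject-level bootstrap inference. Includes a
    synthetic cohort generator with known ground truth (polygenic
    architecture, population stratification, close relatives,
    batch-structured missingness) and readers/writers for PLINK
    bed/bim/fam and GCTA binary GRM files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
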