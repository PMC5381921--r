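Package: regherit
Title: Regional Heritability Mapping with Genomic Relationship Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regional heritability (regional genomic relationship) mapping of
    quantitative traits from dense SNP genotypes. Builds identity-by-state
    genomic relationship matrices on the 0/0.5/1 genotype coding, fits mixed
    models with whole-genome and regional genomic variance components by
    average-information REML, scans sliding 50-percent-overlap SNP windows
    with a boundary-mixture likelihood-ratio test and genome-wide Bonferroni
    thresholds, runs GRAMMAR-style single-SNP association on mixed-model
    residuals, and correlates whole-genome against regional BLUP effect
    predictions across traits. Includes a synthetic multi-trait dairy-style
    data generator with a pleiotropic regional QTL for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
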