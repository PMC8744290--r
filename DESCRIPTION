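Package: svdprs
Title: Polygenic Risk Scores by Singular Value Decomposition Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs polygenic risk scores (PRS) by projecting a target
    cohort onto the singular axes of a discovery cohort's normalized genotype
    matrix. Variants are chosen by LD clumping and p-value thresholding,
    principal components are selected with the eigen-correlation (EigenCorr)
    statistic, and target individuals are scored from out-of-sample principal
    component coordinates. Includes the conventional clumping-and-thresholding
    PRS with principal-component-adjusted marginal effects as a baseline, a
    reference-panel ancestry classifier based on Fisher linear discriminants,
    a structured-GWAS simulator under the Balding-Nichols model, PLINK binary
    fileset input/output, and grid-search evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
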