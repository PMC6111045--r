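Package: methylaccel
Title: Epigenetic Age Acceleration and Risk-Factor Association in Pedigreed Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying DNA methylation age acceleration in family-based
    cohorts: detection-p/beadcount quality control of methylation beta matrices,
    clock-based epigenetic age prediction with pluggable coefficient tables,
    reference-based blood cell deconvolution, intrinsic and extrinsic epigenetic
    age acceleration (IEAA/EEAA, the latter via a Klemera-Doubal weighted
    biological age), clumping-and-thresholding polygenic scores, and
    pedigree-aware mixed-model association of acceleration with risk factors
    under Bonferroni control. Includes a synthetic-cohort generator (pedigrees,
    phenotypes, clock-structured methylation with injected QC failures, toy
    genotypes) providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
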