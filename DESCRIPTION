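Package: prspipe
Title: Genome-Based Polygenic Risk Scoring, Cohort Statistics and
    Coverage QC for Hereditary Cancer Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running a clinical-genome hereditary breast and
    ovarian cancer (HBOC) analysis end to end: reading and harmonizing
    PGS-Catalog-style polygenic score models against VCF genotypes
    (including strand-flip and palindromic-variant resolution), computing
    raw polygenic risk scores with control-cohort z-score calibration and
    empirical percentile banding, exporting CanRisk-compatible PRS
    blocks, cohort-level statistics (normality-gated two-sample tests,
    Cohen's D, rank effect sizes, Poisson-binomial expected-vs-observed
    diagnostic-yield testing, finding-rate panels), per-gene sequencing
    depth-gap QC over exon targets, and a fully deterministic synthetic
    cohort generator under a liability-threshold disease model for
    validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    withr,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
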