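Package: methdev
Title: Differential Methylation and Co-Methylation Network Analysis for
    Brain 450K Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for case-control epigenome-wide
    association studies on Illumina 450K-style methylation data: quality
    control by detection p-value and beadcount, type-stratified
    between-sample quantile normalization, probe-wise differential
    methylation on M-values with optional empirical-Bayes variance
    moderation, region-level aggregation, neuronal-proportion
    deconvolution and sensitivity reanalysis, weighted co-methylation
    network modules with eigengenes and module preservation,
    cross-cohort replication of effect sizes, and a permutation test of
    enrichment for fetal-brain developmental trajectories. Includes a
    synthetic-data generator with machine-readable planted truth for
    validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
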