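Package: cllmeth
Title: Case-Control DNA Methylation Analysis for Chronic Lymphocytic Leukaemia
Version: 0.1.0
Authors@R:
    person("CLL Methylation", "Pipeline Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: A reusable pipeline for Illumina 450K-style case-control DNA
    methylation studies of chronic lymphocytic leukaemia (CLL) and related
    B-cell conditions: sample and probe quality control, probe-type-aware
    quantile normalization, beta/M-value transformation, empirical-Bayes
    batch correction, per-probe differential methylation with effect-size
    and FDR criteria, differentially methylated region calling, copy-number
    profiling from total probe intensity, negative-binomial RNA-seq
    differential expression, direction-consistent cross-cohort replication,
    promoter/body direction-class integration of methylation and
    expression, RBF-SVM methylation subtyping, and subtraction of
    B-cell-differentiation CpGs. Ships a fully parameterised synthetic-data
    generator with a ground-truth ledger so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
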