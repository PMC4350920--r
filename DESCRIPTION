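Package: methweave
Title: Ancestry-Dependent DNA Methylation and Co-Methylation Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for epigenome-wide association analysis of
    promoter-array DNA methylation in two-ancestry cohorts: detection p-value
    masking and probe filtering, beta/M-value transforms, empirical-Bayes batch
    correction, reference-based leukocyte deconvolution, covariate-adjusted
    per-CpG linear models with Benjamini-Hochberg false-discovery control,
    two-criterion cross-cohort replication filtering, hypergeometric
    set-enrichment testing, and weighted co-methylation network analysis
    (soft-threshold adjacency, topological overlap, module eigengenes,
    module-trait interaction models). Includes a seeded synthetic cohort
    generator that reproduces the statistical structure the analysis assumes,
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    sva
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
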