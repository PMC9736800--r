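Package: scMetR
Title: Per-Cell Metastatic Risk Scoring for Tumor Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates per-cell metastatic risk in tumor single-cell RNA-seq
    data by combining a single-sample GSEA score of EMT-associated gene
    activity with a differentiation-potential score, standardizing their sum
    into the scMetR score, and classifying tumor sub-clusters into
    metastasis-featuring, transitional, and conventional tiers. Downstream
    tools derive metastatic signature genes by Wilcoxon differential
    expression, test their over-representation in user-supplied gene-set
    collections, stratify bulk survival cohorts at an optimal log-rank
    cutpoint, and screen drug perturbation profiles for signature reversal
    via Prototype Ranked List merging and preranked GSEA. A synthetic-data
    module generates single-cell, bulk-survival, and drug-profile fixtures
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    survival,
    cluster,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
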