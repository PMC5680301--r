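Package: pharmclust
Title: Network-Driven Consensus Clustering and Drug-Response Association
    for Cancer Cell Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transcriptome-driven classification of cancer cell line panels
    and downstream pharmacogenomic analysis. Selects high-variance genes by
    the interquartile-range inflexion-point method, builds robust gene
    modules and cell-line clusters by subsampled hierarchical consensus
    clustering (Pearson distance, Ward linkage), prunes modules against a
    scored gene-gene interaction network, quantifies cross-dataset
    clustering concordance, characterizes clusters by differential
    expression, pre-ranked gene set enrichment, mutation enrichment, EMT
    signature labels and receptor-status mixture calls, and tests
    cluster-drug sensitivity associations (pseudo-F partition comparison,
    Welch t phenotype calls, FDR control). Includes a paired synthetic-panel
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
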