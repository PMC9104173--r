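Package: stromastage
Title: Stage-Resolved Fibroblast Analysis of Pancreatic Tumor Stroma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a fibroblast-centric analysis of pancreatic ductal
    adenocarcinoma single-cell transcriptomes across metastatic stages:
    normalization, PCA, shared-nearest-neighbor Louvain clustering, marker
    calling and cluster-by-stage proportions; a product-form ligand-receptor
    interaction strength; preranked gene set enrichment with a permutation
    null and leading-edge extraction; a within-gene-set co-expression test;
    short-series stage-pattern mining; protein-protein-interaction subnetwork
    extraction with linker genes; and quantification of nanopatterned stromal
    invasion assays (front profiles, fork calling, depth comparison). A
    negative-binomial synthetic-data generator with planted structure makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    matrixStats,
    igraph,
    yaml,
    RANN,
    Rtsne,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
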