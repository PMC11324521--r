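Package: commshift
Title: Permutation-Based Ligand-Receptor Scoring and Differential
    Cell-Cell Communication for scRNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring condition-differential cell-cell
    communication from single-cell RNA-seq count data. Implements barcode
    and gene quality control with a library-complexity statistic, depth
    normalization, highly-variable-gene selection and capped scaling;
    pseudobulk negative-binomial Wald differential expression with
    one-vs-many aggregation (mean log2 fold change, Fisher-combined
    adjusted p-values) and radial-plot preparation; a product-based
    ligand-receptor interaction score (LRIScore) with a cell-type-label
    permutation null, Benjamini-Hochberg correction and z-scores; a
    condition-differential communication score (LRIDiffScore) with a
    direction-sensitive condition-label permutation test; and
    pseudotime-binned gene-module detection via thresholded correlation
    networks and Leiden clustering. A negative-binomial simulator with
    planted ligand-receptor effects and temporal gene programs provides
    ground truth for end-to-end validation.
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
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
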