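Package: scEnhance
Title: Similarity-Regularized NMF Enhancement of Single-Cell Chromatin
    Accessibility Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Enhancement (denoising/imputation) of sparse single-cell
    chromatin accessibility (scATAC-seq) peak-by-cell matrices. The core
    model couples non-negative matrix factorization to an iteratively
    optimized cell-to-cell similarity matrix under a random binary mask,
    using projected gradient descent with closed-form adaptive step sizes
    for the projection and similarity factors and a backtracked step for
    the cell embedding. A reference-anchored variant ties part of the
    projection matrix to a basis extracted from bulk or pseudo-bulk
    profiles. The package also provides TF-IDF preprocessing, peak-level
    interpretation of the fitted factors, a clustering/metric evaluation
    suite, and a discrete-cluster synthetic data generator with dropout
    and subsampling corruptions so the whole pipeline can be exercised
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    mclust,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: SingleCell, Epigenetics, ATACSeq, Preprocessing, Clustering,
    DimensionReduction
RoxygenNote: 7.3.3
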