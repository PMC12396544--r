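Package: markerForest
Title: Minimal Marker Gene Combinations for Cell Type Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selects minimal combinations of necessary and sufficient marker
    genes for cell type clusters in single-cell RNA-seq data. Candidate genes
    are pre-filtered by a binary expression score computed on cluster medians,
    ranked per cluster with a one-versus-all random forest by Gini importance,
    re-ranked by binary score, and combined with AND logic over single-split
    decision-tree expression cutoffs; the combination maximising the F-beta
    score is reported together with precision, recall, confusion counts and an
    on-target expression fraction. Includes a standalone evaluator for
    user-supplied marker lists and a zero-inflated mixture simulator for
    validating marker selection without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    matrixStats,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    rhdf5,
    jsonlite,
    data.table,
    ggplot2,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
biocViews: SingleCell, Transcriptomics, GeneExpression, Classification,
    FeatureExtraction, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
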