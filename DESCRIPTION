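Package: unbgcn
Title: Univariate Neurodegeneration Biomarkers and Population-Graph
    Convolutional Classification of Cortical Atrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes univariate neurodegeneration biomarkers (UNB) from
    vertex-wise cortical-thickness tables by scoring the similarity of an
    individual's atrophy z-score pattern against a disease-group atrophy
    pattern per region of interest, and classifies subjects with a
    semi-supervised spectral graph convolutional network over a
    phenotype-similarity population graph with a dot-product attention
    module. Includes a synthetic-cohort generator with planted atrophy
    effects, covariate adjustment via per-vertex linear models, graph
    operators (phenotype adjacency, normalized Laplacian, renormalized
    propagation), repeated-split cross-validation and grid search, and a
    longitudinal evaluation suite (minimum sample size, change rates,
    paired effect sizes, Pearson correlations, rank-based ROC/AUC with
    bootstrap confidence intervals).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
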