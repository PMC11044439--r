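Package: medwgcna
Title: Causal Weighted Co-Expression Network Analysis with Mediation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extends the weighted gene co-expression network (WGCNA)
    workflow with causal mediation inference. Builds soft-thresholded
    correlation networks and topological-overlap modules from omics
    matrices, tests module eigengenes and within-module features for
    phenotype association with an empirical-Bayes moderated t-statistic,
    and classifies differential features as phenotype drivers or
    passengers by fitting forward (module - feature - phenotype) and
    reverse (phenotype - feature - module) mediation models with the
    product method and stabilized inverse-probability weights. Also
    provides network-topology-aware gene-set annotation by edge-weight
    permutation, multi-omics sample clustering through iterated canonical
    correlation analysis or concatenated module eigengenes, and an
    imbalance-aware SMOTE-bagging ensemble classifier with elastic-net
    feature selection. A synthetic-data module generates block-correlated
    modules, planted mediation chains with confounding, shared multi-omic
    cluster structure and imbalanced class labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    cluster,
    glmnet,
    e1071,
    nnet,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    car,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
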