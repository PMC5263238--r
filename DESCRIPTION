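Package: neuroAging
Title: Multi-Region Brain Aging Transcriptomics and Immunohistochemistry
    Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying transcriptional and cellular changes in the
    aging human brain. Implements per-region three-age-group differential
    expression with false discovery rate control and regional-breadth
    classification of aging-altered genes; cell-type specificity scoring and
    marker derivation from reference expression profiles; sample
    classification by correlation, hierarchical clustering and t-SNE with
    age-group discrimination scoring; stepwise age-associative regression with
    cohort covariates and gene-gene interactions; an immunohistochemistry tile
    quantification pipeline (entropy quality control, channel-based
    segmentation of chromogen-stained and counterstained cells, size binning,
    density-class tile selection); and shuffled-label permutation statistics
    on per-tile counts. A synthetic-data module generates expression cohorts,
    cell-type references and stained-tile images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    Rtsne,
    ape,
    png,
    jsonlite,
    withr,
    igraph
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, CellBiology, Regression,
    DifferentialExpression
RoxygenNote: 7.3.3
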