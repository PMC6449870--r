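Package: reprophen
Title: Phenotypic Profiling and Progression Analysis for Early Reprogramming Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-content RNAi screens of early somatic-cell
    reprogramming. Normalizes per-well colony feature tables to per-plate Z-scores,
    removes redundant features by pairwise correlation, clusters knockdown phenotypes
    with K-means, and ranks hits by correlation to positive-control phenotypes combined
    with an ensemble machine-learning facilitator score. A transcriptome component
    computes knockdown-to-knockdown expression correlations, cross-modal concordance
    with the imaging phenotypes, and a reprogramming-progression model that projects
    samples onto a second-order polynomial curve fitted to a rotated two-dimensional
    PCA embedding of a reprogramming time course, yielding a pseudotime proxy and an
    off-trajectory residual. Functional interaction between gene pairs is tested from
    single- and double-knockdown colony counts under a multiplicative expected-ratio
    model. A synthetic-data generator with planted ground truth supports end-to-end
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
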