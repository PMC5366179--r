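Package: cedeg
Title: Class-Enhanced Differential Expression and Biomarker Discovery for
    Multi-Class Transcriptomic Studies
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for biomarker discovery in multi-class gene
    expression studies such as large leukaemia cohorts: RMA-style
    preprocessing (normal+exponential background correction, quantile
    normalisation, median-polish summarisation), empirical-Bayes batch
    adjustment with diagnostic PCA and Kruskal-Wallis/two-way-ANOVA
    verification, adaptive gene filtering by one-dimensional Gaussian
    mixture decomposition, assumption-routed multi-group testing
    (ANOVA with Dunnett many-to-one comparisons, or Kruskal-Wallis with
    Games-Howell pairwise post-hoc tests), selection of class-enhanced
    differentially expressed genes (CE-DEGs) and single-class biomarkers,
    Dice set-similarity statistics with bootstrap confidence intervals,
    Fisher-exact term enrichment, and a repeated stratified
    cross-validation classification study with a linear support vector
    machine. A synthetic-data generator with planted ground truth makes
    every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    sva,
    mvtnorm,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    multcomp,
    car,
    cluster,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
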