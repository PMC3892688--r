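Package: stagefly
Title: Developmental Stage Annotation of Drosophila Embryo Expression Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated annotation of developmental stages (3-17) for
    standardized Drosophila melanogaster embryo gene-expression images.
    Texture features are extracted with a log-Gabor filter bank and
    block-mean down-sampling; a pool of diverse sparse linear classifiers
    (Lasso, group Lasso and sparse group Lasso with least-square and
    logistic losses, plus a linear hinge-loss SVM) is trained over many
    random train/validation partitions; confidence-weighted voting over the
    pool yields a stage, an early/late sub-stage, and a continuous stage
    score used to order embryos along developmental time. Includes
    evaluation criteria at stage and sub-stage resolution, aggregation of
    expression images into stage-wise expression maps, and a synthetic
    embryo-image generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
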