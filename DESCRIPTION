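Package: urisedclass
Title: Hybrid Texture and Deep Feature Classification of Urine Sediment Particles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification pipeline for microscopy images of urine sediment
    particles (erythrocytes, leukocytes, crystals, casts, epithelial cells,
    bacteria, yeast). Extracts uniform Local Binary Pattern texture
    descriptors (59-bin histograms over a 7x7 cell grid, 2891 features) and
    1000-dimensional dense image features, reduces each block to 500
    dimensions by greedy minimum-redundancy maximum-relevance (mRMR)
    selection with mutual-information or F-test criteria, fuses the blocks
    into a 1000-column feature matrix, and benchmarks six classical
    classifiers (decision tree, regularized linear discriminant, Gaussian
    naive Bayes, linear SVM, k-nearest neighbours, bagged trees) under
    stratified holdout or cross-validation, reporting per-class confusion
    matrices and precision/recall/specificity/FDR/FPR/FNR/F1 tables. Includes
    a seeded synthetic textured-particle image generator so the entire
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    data.table,
    e1071,
    class,
    rpart,
    randomForest,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
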