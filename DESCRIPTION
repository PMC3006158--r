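Package: geneDoublets
Title: Gene-Pair Doublet Features for Two-Class Expression Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs gene-pair "doublet" features (elementwise sum,
    difference, product, and sign-of-difference of gene expression vectors)
    from a two-class genes-by-samples expression matrix, ranks genes and
    doublets by a two-sample t-score, greedily selects unique doublets so
    that no gene appears in more than one pair, and evaluates
    doublet-augmented classifiers against raw-expression baselines with a
    leakage-free leave-one-out cross-validation harness in which all feature
    selection is recomputed inside every fold. Includes native k-nearest-
    neighbour, Gaussian naive Bayes and nearest-shrunken-centroid
    classifiers, a synthetic two-class expression generator with planted
    single-gene, shared-noise pair, and order-reversal pair signal, and
    TSV/JSON readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    rpart,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
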