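Package: miRatio
Title: MicroRNA Expression-Ratio Signatures for Two-Group Tumor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates microRNA (miRNA) expression-ratio diagnostic
    signatures for two-group designs such as borderline versus malignant ovarian
    tumors. Provides candidate selection from a normalized two-group log2
    expression matrix (fold-change and expression filters, single-threshold
    classification-error counts), grouped reference-gene stability scoring in
    the NormFinder style with geometric-mean normalization, replicate
    aggregation and 2^-deltaCq / 2^-deltadeltaCq RT-qPCR quantification,
    construction of all up/down miRNA expression ratios with equal-variance
    t-tests, ROC curves and Youden-index optimal cutoffs, and an exhaustive
    search over admissible pairs of ratios ("double ratios") scored by
    resubstitution classification errors. A synthetic-data generator with known
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
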