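Package: flightDE
Title: Factorial Differential Expression and Cross-Contrast Gene
    Classification for Genotype-by-Environment Transcriptomics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-dimensional comparative transcriptomics for 2x2
    genotype-by-environment designs. Fits per-gene cell-means linear
    models with empirical-Bayes moderated t-statistics (scaled
    inverse-chi-square variance prior estimated by digamma/trigamma
    moment matching), Benjamini-Hochberg false discovery rate control,
    and thresholded differential-expression calls for the four canonical
    contrasts of a wild-type/knockout x ground/flight experiment. Genes
    are then classified by their cross-contrast significance pattern
    into shared, required, corrected, genotype-dependent, compensated
    and persistent-genotype-difference categories. Includes quantile
    normalization and detection-call filtering for summarized microarray
    matrices, one-sided Fisher (hypergeometric) term enrichment against
    a user-supplied annotation, and a synthetic-data generator with
    planted effects and a ground-truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
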