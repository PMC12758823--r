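Package: fkgmm
Title: Multi-Modal Image and Tabular Fusion with Fuzzy Knowledge Graph Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for fuzzy-knowledge-graph based decision support on paired
    retinal-fundus-style images and clinical tabular records. Extracts gray-level
    co-occurrence (GLCM) texture and first-order statistical features from
    preprocessed images (unsharp masking, non-local-means denoising, CLAHE, Otsu
    lesion masking), cleans and balances clinical tables, fuses the two feature
    sets by five alternative strategies (importance ranking, low-rank tensor
    product, Hadamard product, correlation-pruned filter, and wrapper-based
    sequential forward selection), compiles labeled features into a fuzzy rule
    base, builds and samples a fuzzy knowledge graph, and classifies records by
    additive fuzzy inference. Includes a seeded synthetic paired-data generator
    and one-way ANOVA / Tukey HSD comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
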