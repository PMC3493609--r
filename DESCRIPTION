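Package: lipidisc
Title: Targeted Lipidomics Cohort Analysis with OPLS-DA and Iterative
    Variable Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for comparing targeted plasma lipidomics panels
    (non-esterified fatty acids, oxylipins, endocannabinoids) between two
    clinical cohorts. Provides quality-control reporting filters, geometric
    mean summaries with percent-change effect sizes, Mann-Whitney U tests
    under Benjamini-Hochberg false discovery rate control, enzyme activity
    indices from product-to-substrate ratios, NIPALS PLS-DA and OPLS-DA
    discriminant models with cross-validated Q2 and AUROC, a stochastic
    forward/backward wrapper for iterative variable selection, Spearman
    correlation parameter-connectivity networks with multidimensional
    scaling and Hotelling T2 class ellipses, and a seeded synthetic cohort
    generator for end-to-end validation of the chain.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
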