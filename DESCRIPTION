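Package: seqpad
Title: Padding Strategies for One-Hot-Encoded Amino Acid Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bringing amino acid sequences to a common length
    before one-hot encoding, and for measuring what that choice does to a
    downstream classifier. Implements seven padding strategies (post-, pre-,
    mid-, ext-, strf-, rnd- and zoom-padding) plus padding-based data
    augmentation, a one-hot codec with an explicit pad row, a synthetic
    motif-planted protein generator, a hierarchical enzyme-classification
    benchmark (enzyme/non-enzyme, then the first EC digit) over three small
    neural architectures trained natively in R, per-label and macro F1 /
    accuracy / AUC metrics with paired Wilcoxon comparisons, PCA of
    convolutional-filter activations, and treatment-coded explanatory linear
    models with Benjamini-Hochberg adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
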