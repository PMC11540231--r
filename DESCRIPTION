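Package: fewsubspace
Title: Subspace Feature Representations for Few-Shot Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Few-shot classification of high-dimensional image features via
    subspace representations. Implements between/within-class scatter
    statistics, regularized multiclass Fisher discriminant analysis,
    recursive orthogonal (Foley-Sammon) discriminant vectors with
    discrim-values for binary problems, PCA/SVD subspaces, non-negative
    matrix factorization by multiplicative updates and a supervised NMF
    variant, plus an episode-based evaluation protocol (per-class
    train/test splits, K-averaged nearest-neighbour accuracy over repeated
    samplings, and a Z-test for comparing arms). Includes seeded synthetic
    generators (class-structured Gaussian mixtures, variance-trap mixtures,
    planted low-rank non-negative matrices) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    e1071,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
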