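Package: omicsfa
Title: Sparse Factor Analysis for Multi-Omics Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates multiple molecular data types (expression, copy number,
    protein arrays) measured on the same samples into a small number of
    continuous latent factors by a sparse factor analysis: a penalized EM
    algorithm with elastic-net coordinate-descent coefficient updates and
    unit-variance factor rescaling. Includes BIC-driven penalty selection with
    Tibshirani-Taylor effective degrees of freedom, a factor-tailored gene-set
    enrichment analysis with a sample-permutation null, explained-variance
    decomposition per factor and data type, single-sample and cross-platform
    factor projection, and a synthetic multi-omics generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
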