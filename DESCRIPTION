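Package: sitr
Title: Two-Tier Codebook Assessment of Self-Injury Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and applies a text-assessment machine for free-text
    self-injury narratives. From a labeled training corpus it fits
    per-subset latent Dirichlet allocation (LDA) topic models by collapsed
    Gibbs sampling, composes a scored codebook of key tokens with
    representativeness scores and a risk lexicon, and assesses new
    writings through a two-tier hierarchy: weighted subset scoring (H1)
    followed by topic-profile matching against training cases (H2).
    Includes the psychometric statistics used to calibrate and validate
    such a machine (Cohen's kappa, ICC(2,k), one-way MANOVA, hierarchical
    regression with R-squared change), a synthetic labeled-corpus
    generator for evaluation, and report rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringi,
    jsonlite,
    generics,
    ggplot2,
    car,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
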