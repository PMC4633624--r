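Package: mutascope
Title: Reporter-Based Mutation-Rate Estimation, Mutational Spectra and
    Amplicon Deep-Sequencing Mutation Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for quantifying in vivo bacterial
    mutagenesis. Implements the reporter-based (rifampin-resistance)
    fluctuation-assay mutation-rate estimator and derived rate arithmetic,
    twelve-class mutational-spectrum classification with complement
    collapsing, substitution extraction from single-clone reporter
    sequences with amino-acid change naming, a background-subtracted
    amplicon deep-sequencing mutation caller, a Poisson model of lacZ
    blue/white plaque inactivation, and forward-time synthetic-data
    generators with machine-readable ground truth for every assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    Biostrings,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    knitr
Config/testthat/edition: 3
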