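Package: pmadbench
Title: Benchmarking of Proteomic Intensity Processing Chains by Replicate Precision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exhaustive evaluation of transformation, normalization and
    missing-value imputation chains for label-free (DIA/SWATH-MS) protein
    intensity matrices. Implements a registry of 25 processing methods plus
    the identity option at every stage (560 chains in total), scores every
    chain on every dataset with the pooled intragroup median absolute
    deviation (PMAD) precision metric, and identifies consistently
    well-performed analysis chains by Ward hierarchical clustering of
    per-chain PMAD profiles across datasets. Ships a synthetic-data
    generator emulating two-group SWATH-MS designs with per-sample scaling
    bias, heteroscedastic noise and intensity-dependent missingness, so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR
Config/testthat/edition: 3
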