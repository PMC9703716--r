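Package: scnthick
Title: Structural Covariance Networks from Regional Cortical Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Group-level analysis of regional cortical thickness tables:
    demographic and per-region group comparisons with Bonferroni control,
    clinical correlation batteries (Spearman and point-biserial),
    construction of density-thresholded structural covariance networks,
    binary graph metrics with small-world normalization against
    degree-preserving rewired nulls, permutation-based between-group
    comparison of metric curves and their areas under the curve with
    Benjamini-Hochberg control, and betweenness-based hub identification.
    Includes a synthetic two-group cohort generator with block-modular
    inter-regional correlation, covariate effects, planted hubs, and
    coupled clinical variables, so the full pipeline is testable without
    access to subject-level imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
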