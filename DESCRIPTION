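Package: topreg
Title: Topological Regression and Adaptive Anchor Selection for QSAR Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Similarity-based quantitative structure-activity relationship
    (QSAR) modeling by topological regression: ridge regression from
    structure-space distances to response-space distances over anchor
    molecules, with k-means response-anchor selection, adaptive structure
    anchor selection, and radial-basis-function or optimization-based
    response reconstruction. Includes molecule table input with SMILES
    validation, circular and min-hash fingerprints, drug-blind
    cross-validation, weight-based model interpretation, ensemble and
    stacking variants, a Monte-Carlo verification suite for the method's
    Bayesian hierarchical formulation, and a synthetic data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
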