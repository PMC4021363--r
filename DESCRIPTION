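Package: rrrstab
Title: Stability of Reduced Rank Regression Dietary Patterns Across Repeated Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving dietary patterns by reduced rank regression (RRR)
    of food-group intakes on cardiovascular risk factors, and for assessing how
    stable those patterns are across repeated dietary surveys. Includes
    backwards-elimination screening of food groups, pattern-count selection by
    Monte-Carlo cross-validated PRESS with Van der Voet's paired randomization
    test, exploratory and confirmatory (fixed-weight) pattern scoring across
    measurement waves, energy-residual adjustment, cross-wave descriptive
    statistics for skewed intakes, and a synthetic two-wave cohort generator
    with known latent patterns for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
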