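Package: ecolink
Title: Facility Sampling and Ecological Linking for Effective Coverage
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how sampling health facilities affects effective
    coverage estimates obtained by ecologically linking household-survey
    care-seeking data to facility-assessment quality scores. Implements
    exact-match, Euclidean-nearest and administrative-unit caseload-weighted
    linking with provider-category fallback rules; crude, input-adjusted and
    quality-adjusted coverage with design-based confidence intervals treating
    household clusters as primary sampling units; SPA-style facility sampling
    that keeps a census of referral facilities; random and preferential
    quality-score simulations; a synthetic region generator; and a scenario
    runner that compares sample-derived estimates against census and
    exact-match references.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
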