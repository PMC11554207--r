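Package: floodcontam
Title: Contamination Indices and Temporal Trends for Invaded Fish
    Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies long-term contamination of native fish assemblages
    by non-native species in floodplain monitoring surveys.  Provides
    area-standardised biomass, five contamination indices (richness,
    biomass, ecosystem, additive and geometric forms), Kempton's Q
    interquartile biomass diversity, biomass-richness rank correlations
    with exact small-sample inference, penalized-spline temporal trends
    with AR(1) residual correlation and locality random intercepts,
    nonparametric group comparisons, and a seeded generator of synthetic
    floodplain survey data with gear selectivity and flood-pulse-driven
    colonization for end-to-end validation and parameter-recovery
    experiments.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    mgcv,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
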