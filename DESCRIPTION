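Package: grassfire
Title: Fire-Regime Statistics and Persistence Strategies of Fire-Prone Grasses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives species-level fire-regime statistics from occurrence
    records and satellite burn histories, and relates them to plant
    persistence strategy on a phylogeny. Implements occurrence-record quality
    control, inter-fire interval extraction with right-censored open tails,
    censored Weibull survival fitting of the fire return interval, break-point
    regression to delimit fire-prone species, fire-radiative-power quantile
    summaries, Foley's drought index from monthly rainfall, phylogenetic
    logistic regression of a binary seeder/resprouter strategy with Firth-type
    penalization and parametric bootstrap intervals, phylogenetic generalized
    least squares, and leaf-trait principal components. A synthetic-data
    module simulates Weibull-renewal fire histories, seasonal rainfall with
    drought episodes, birth-death phylogenies and binary traits with tunable
    phylogenetic signal, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    graphics,
    stats,
    utils
Suggests:
    survival,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
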