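Package: gwtrends
Title: Geographically Weighted Regression for Temporal Trends in Sparse
    Monitoring Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates spatially varying temporal trends in environmental
    monitoring data that cover many stations but hold only a few observations
    per station, such as rotating-panel lake surveys. Adapts geographically
    weighted regression (GWR) by using calendar time as the explanatory
    variable and pooling observations across a bisquare-weighted adaptive
    k-nearest-neighbour window, so a trend slope can be estimated for every
    station even when individual series are too short for station-wise
    methods. Includes log10 pre-processing, station-wise mean-centering, a
    log-normal coefficient-of-variation outlier screen, a Moran's I
    heterogeneity diagnostic on crude per-station changes, leave-one-out
    cross-validation for the neighbourhood size, moving-window fits for
    detecting nonlinearity, multi-program merging, and a synthetic
    rotating-panel survey generator for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cli,
    dplyr,
    generics,
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
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
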