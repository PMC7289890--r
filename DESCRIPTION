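Package: dryflux
Title: Eddy-Covariance CO2 Flux Processing and Carbon Balance for
    Seasonally Dry Tropical Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Half-hourly eddy-covariance CO2 flux processing for
    seasonally dry tropical ecosystems: turbulent flux and storage-term
    computation, moving-median despiking, friction-velocity (u*)
    threshold estimation by the moving point test, marginal distribution
    sampling (MDS) gap-filling, nighttime Lloyd-Taylor partitioning of
    net ecosystem exchange into gross primary production and ecosystem
    respiration, rectangular-hyperbola light-response fitting, and
    seasonal/annual carbon accounting with bootstrap confidence
    intervals. Includes a synthetic-data generator that emulates a
    semiarid flux-tower site with known ground truth so every stage of
    the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    zoo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
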