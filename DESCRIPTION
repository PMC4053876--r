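Package: paqr
Title: Particulate Air Quality Assessment with Satellite-Driven PM Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for particulate-matter pollution and population-exposure
    assessment. Estimates gridded PM10/PM2.5 concentrations from satellite and
    reanalysis predictors with a Levenberg-Marquardt back-propagation neural
    network (with stepwise partial-F predictor screening and repeated
    random-sampling training), maps concentrations to individual air-quality
    indexes by breakpoint interpolation, combines them into a composite
    particulate air-quality index (PAQI) with extreme-value weight
    modification, and computes per-capita and population-weighted PM2.5
    exposure statistics over zonal masks. Ships a seeded synthetic-data
    generator of co-registered predictor rasters, population density and zone
    masks so the full chain is testable without external data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
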