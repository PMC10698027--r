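Package: shorecast
Title: Seasonal Forecasting of Coastal Management Indices with Skill
    Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Drives two sea-surface-temperature based marine management
    indices - the Habitat Compression Index for whale entanglement risk
    and a loggerhead bycatch closure indicator built on six-month mean
    SST anomalies - with multi-member seasonal forecast ensembles, and
    verifies the resulting retrospective forecasts. Provides a synthetic
    gridded-SST generator (an observed reanalysis analog plus forecast
    ensembles with lead-dependent drift and skill decay, including
    multi-year marine heatwaves), coastal distance-band and box masks on
    a spherical Earth, per-member and per-lead drift-correcting
    climatologies, ensemble construction for global versus downscaled
    forecast configurations, and a verification suite with
    autocorrelation-corrected correlation significance (effective
    degrees of freedom and Fisher-Z intervals), forecast accuracy
    against a random-forecast baseline, the Symmetric Extremal
    Dependence Index, and bootstrap significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ncdf4,
    optparse,
    testthat (>= 3.0.0),
    zoo
Config/testthat/edition: 3
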