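Package: rwudiel
Title: Root Water Uptake from Diurnal Soil Moisture Fluctuations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates grassland root water uptake (RWU) from diurnal
    fluctuations in multi-depth soil water content time series. Implements
    the day/night slope-regression estimator with vertical-flow correction
    (daily and polynomial hourly variants), depth-weighted integration over
    the main rooting horizon, decile-binned RWU/SWC and RWU/VPD response
    surfaces with diel hysteresis metrics, maximum hourly uptake capacity
    per soil layer, and fine-root trait computation (specific root length
    and area, mass density, root-to-shoot production) with simple linear
    trait-uptake relations. A multi-layer bucket soil-water simulator with
    a VPD-driven transpiration sink, treatment forcings (warming, stomatal
    down-regulation, rain exclusion) and a sensor-artefact model provides
    ground truth for recovery testing, alongside the soil-moisture quality
    control chain (range filter, hourly-median smoothing, gap filling,
    single-step spike removal).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
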