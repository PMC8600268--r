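Package: hopperdev
Title: Thermal Developmental Plasticity and Phenology of Montane Grasshoppers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how diurnal temperature variation and
    photoperiod shape insect development, growth, and seasonal timing.
    Implements square-wave rearing-regime summaries via constant temperature
    equivalents (CTE) under exponential (Q10) rate models, nonlinear
    least-squares fitting of fluctuating-temperature Q10 models for
    development time and adult mass with relative normalisation, growing
    degree-day accumulation from daily minimum and maximum temperatures by
    the single-sine approximation, and estimation of adult phenology as the
    day of year or cumulative degree-days at which a smoothed development
    index crosses a threshold. A synthetic-data module generates rearing
    cohorts, daily weather series, and stage-count field surveys that
    emulate a factorial temperature-variance by photoperiod experiment on
    montane grasshopper populations along an elevation gradient, so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
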