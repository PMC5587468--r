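Package: soilresp
Title: Soil CO2 Efflux Analysis for Seasonal Tropical Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing soil respiration measured with closed dynamic
    chambers in seasonal tropical forests: computation of CO2 effluxes from raw
    chamber concentration traces (linear and exponential fits with deadbands
    and a quality-control cascade), quadratic soil-moisture response curves
    with robust fitting, detection and regression of rain-induced (Birch
    effect) respiration pulses, spatiotemporal variability statistics
    (coefficients of variation, temporal autocorrelation of flux anomalies,
    semivariograms, dry-season diurnal composites with phase lags), ensemble
    feed-forward neural-network gap-filling with inverse-MSE weighting,
    integration to seasonal and annual soil carbon budgets, and a multiway
    ANOVA of moisture-detrended spatial variation. A calibrated synthetic-data
    generator emulates the chamber network of a Barro Colorado Island-like
    moist forest so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    minpack.lm,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
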