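Package: forestflux
Title: Carbon Dynamics of Long-Term Tropical Forest Inventory Plots Under
    Climate Anomalies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the live-biomass carbon response of
    long-term tropical forest inventory plot networks to short-term
    climate anomalies such as El Nino events.  Provides stem-census
    quality control (growth and shrinkage screens, point-of-measurement
    changes, single-measurement imputation), height-diameter Weibull
    allometry and wood-density based aboveground biomass and carbon
    accounting, census-interval bias correction of demographic and
    carbon fluxes under a constant-instantaneous-rates model, plot-level
    climate reconstruction (two-dataset monthly harmonization,
    climatology downscaling with lapse-rate adjustment, maximum
    cumulative water deficit), anomaly attribution by weighted
    regression with AIC multimodel averaging, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
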