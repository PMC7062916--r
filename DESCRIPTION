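Package: tmfcarbon
Title: Carbon Stock Estimation and Altitudinal Trend Analysis for Tropical Montane Forest Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates plot-level carbon stocks in tropical montane forest
    inventories and analyses their altitudinal and climatic trends. Computes
    per-tree aboveground biomass from the Chave three-variable pantropical
    allometry, liana biomass from a diameter-only power law, coarse-root
    biomass from diameter, and soil organic carbon stocks from core and
    laboratory measurements under the fixed-depth convention. Propagates
    measurement error in diameter, height and wood density into plot stocks by
    Monte Carlo simulation, imputes wood density through a species-to-family
    ladder, derives precipitation seasonality from monthly series, and fits
    Gamma generalized linear models with sequential analysis of deviance and
    explained deviance. Includes a synthetic-study generator with known ground
    truth so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
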