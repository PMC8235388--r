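Package: wheatnar
Title: Stochastic World-Trade CGE Simulation of Wheat-Based Nutrition at Risk
Version: 0.1.0
Authors@R:
    person("wheatnar", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully synthetic re-implementation of a stochastic
    multi-region computable general equilibrium (CGE) pipeline for wheat
    nutrition-security analysis.  The package generates balanced social
    accounting matrices (SAMs) for configurable miniature world economies,
    estimates wheat-productivity volatility from yearly yield series with
    AIC-selected ARIMA models, calibrates a nested CES/CET Armington trade
    model to the benchmark SAM, solves the equilibrium under Monte Carlo
    total-factor-productivity shocks and export-quota scenarios, and converts
    worst-tail household wheat-consumption losses into "Nutrition at Risk"
    percentages of age- and sex-adjusted population nutrient requirements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
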