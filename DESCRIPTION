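Package: larwheat
Title: Carbon-Limited Leaf Appearance Rate Models for Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of wheat main-stem leaf appearance (Haun stage) under
    growth-chamber and field conditions. Provides a beta-function thermal-time
    engine with cardinal temperatures, photothermal quotient (PTQ) arithmetic,
    and three competing leaf-appearance-rate (LAR) models: a constant
    phyllochron, the Sirius segmented-linear model with a sowing-date
    correction, and a carbon supply/demand model in which LAR saturates with
    the ratio of intercepted light to thermal time scaled by an effective
    green area index. Includes observation-side tools (Haun stage from leaf
    measurements, initial LAR, spline-derivative LAR, night carbohydrate
    consumption), model-evaluation statistics (MSE decomposed into squared
    bias, non-unity slope and lack of correlation; RMSRE; Nash-Sutcliffe
    efficiency), RMSRE-minimising parameter estimation, and synthetic
    chamber/field weather generators so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
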