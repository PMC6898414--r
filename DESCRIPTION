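Package: cropbma
Title: Bayesian Model Averaging for Within-Season Weather Effects on Crop Yields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Panel-regression analysis of within-growing-season temperature
    and precipitation effects on county-level maize yields. Converts daily
    minimum/maximum temperatures to monthly growing and heating degree days
    via the single-sine method, builds four nested fixed-effects
    specifications (seasonal and monthly, with and without
    temperature-precipitation interactions), performs closed-form Bayesian
    variable selection and Occam's-window model averaging over the weather
    variables via Markov chain Monte Carlo model composition, evaluates
    specifications by year-blocked cross-validation (RMSE, MAPE, Pearson
    correlation, skill score), and predicts yield impacts of uniform warming
    scenarios and conditional marginal effects of monthly degree days at
    fixed precipitation percentiles. Includes a seeded synthetic weather and
    yield panel generator for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
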