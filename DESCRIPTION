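Package: rmicast
Title: Probabilistic Mortality Forecasting from Rates of Mortality Improvement
Version: 0.1.0
Authors@R: person("rmicast", "maintainers", email = "maintainers@rmicast.org",
    role = c("aut", "cre"))
Description: Tools for stochastic mortality forecasting on age-by-year Lexis
    surfaces. Reads death-rate surfaces in the Human Mortality Database
    single-age dialect, builds period life tables and life expectancy at
    birth, computes and smooths rates of mortality improvement with
    two-dimensional penalized B-splines, and fits three forecasting models:
    the Lee-Carter model, its coherent Li-Lee variant, and a
    rates-of-improvement model with linear age-specific trends and optional
    blending toward pooled reference-country trends. Includes a retrospective
    forecast-evaluation harness (per-year forecast errors and mean absolute
    error), a synthetic-data generator for regular, stagnation-recovery and
    crisis-recovery mortality regimes with coupled reference populations, and
    config-driven reporting with quantile tables, interval widths and
    life-expectancy gains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
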