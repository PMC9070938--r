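Package: nereocast
Title: Winter Ocean Conditions as Predictors of Summer Bull Kelp Canopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quality control and regional aggregation of satellite-derived
    bull kelp (Nereocystis luetkeana) canopy pixels, construction of lagged
    seasonal environmental predictors from monthly ocean indices (MOCI, buoy
    sea-surface temperature, BEUTI), univariate regression screening with
    AIC model selection, leave-one-out precision and predictability-error
    statistics, and forecasting from models trained on the pre-collapse
    period. Includes a synthetic-data generator with known ground truth for
    parameter-recovery and regime-shift (decoupling) experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
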