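Package: bolusrec
Title: Carbohydrate and Insulin Bolus Recommendations from CGM Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Data-driven carbohydrate and insulin bolus recommendation for
    type 1 diabetes self-management. Provides readers for OhioT1DM-style
    pump/CGM event streams (XML and a CSV dialect), meal-bolus timestamp
    anchoring and glucose gap interpolation, construction of inertial and
    unrestricted recommendation examples over a grid of prediction horizons,
    global-average and time-of-day-average baselines, a two-LSTM-chain
    recommendation network and a deep residual stack of such chains with
    backcast/forecast outputs (both implemented with analytic gradients),
    a pretrain-then-personalize training protocol with seed ensembling and
    RMSE/MAE reporting, and a synthetic subject simulator with a closed-form
    recommendation oracle for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
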