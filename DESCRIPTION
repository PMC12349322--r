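Package: glucast
Title: Personalized Probabilistic Glucose Forecasting from Continuous
    Glucose Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-horizon probabilistic forecasting of interstitial
    glucose from continuous glucose monitoring (CGM) traces. Provides a seeded
    synthetic-cohort simulator for two sensor regimes (long CGM-only records at
    15-min sampling with circadian, weekly and seasonal structure, and short
    multivariate records at 5-min sampling with carbohydrate, bolus and basal
    insulin events on heterogeneous timestamps), gap-aware sequence
    construction on a common time grid, a compact temporal-fusion quantile
    forecaster with interpretable variable-selection and attention weights
    trained by pinball loss, diabetes-specific evaluation (ISO 15197:2015
    accuracy zone, Parkes consensus error grid A+B rate, normalized quantile
    risk, interval coverage), and an incremental input-feature study runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
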