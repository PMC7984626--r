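Package: ilistack
Title: Stacked Ensemble Forecasting of Weekly Influenza-Like-Illness
    Visit Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Short-term (1-4 week ahead) probabilistic forecasting of
    weekly influenza-like-illness (ILI) visit counts at a single
    emergency department.  Four member forecasters -- an empirical-Bayes
    model that transforms smoothed past epidemic curves, an STL-adjusted
    ARIMA(2,0,1), a quantile regression forest, and a covariate linear
    regression -- are combined by data-driven stacking with
    simplex-constrained weights estimated by leave-one-season-out
    cross-validation, and by a naive equal-weight ensemble.  Prediction
    intervals for the ensembles are weighted averages of the member
    forecast centiles.  Includes a calibrated synthetic multi-season
    data generator, a full evaluation battery (MAE, RMSE, MAPE, a
    centile-band log score, within-tolerance hit rates, interval
    coverage), and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lubridate,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
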