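Package: bagwormRH
Title: Forecasting Oil-Palm Bagworm Outbreaks from Satellite-Derived Relative Humidity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to predict oil-palm bagworm (Metisa plana) census counts from
    satellite-derived relative humidity (RH). Implements the near-infrared
    channel-ratio retrieval of precipitable water vapour and its conversion to
    an RH raster, area-weighted zonal extraction of block-level RH series,
    assembly of lagged predictor tables (one to six weeks before each census),
    Pearson correlation screening, linear and polynomial regression with
    stepwise selection, and a quickprop-trained multilayer perceptron, together
    with the evaluation metrics used to compare them (mean absolute error,
    min-max accuracy, actual-versus-predicted adjusted R-squared). A synthetic
    estate generator produces scenes with known true RH fields and census
    series with a configurable lagged response, so every stage of the pipeline
    is testable without access to plantation data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
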