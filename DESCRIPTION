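Package: torrid
Title: Torridity-Index Heatwave Detection and Hazard Assessment for Daily Climate Grids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects heatwaves in daily maximum-temperature and relative-humidity
    series or grids using a humidity-adjusted torridity index, locally calibrated
    median-of-hot-days thresholds, and a cumulative daily heat index. Extracts
    annual hazard indicators (frequency, peak intensity, maximum duration),
    combines them into a normalized composite hazard score with per-pixel linear
    trends and relative-change diagnostics, classifies hazard surfaces with exact
    Fisher-Jenks natural breaks into a four-category spatiotemporal typology, and
    ranks user-supplied zones. Includes a synthetic climate generator with known
    injected heat episodes for ground-truth validation, and an interpolation
    cross-validation metric suite (MAE, NMAE, RMSE, NRMSE, truth-on-prediction
    regression).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
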