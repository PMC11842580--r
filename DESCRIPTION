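Package: cdi
Title: Combined Drought Indicator for Agricultural Drought Monitoring
Version: 0.4.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the Combined Drought Indicator (CDI), a seven-class
    per-pixel drought classification for agricultural drought monitoring on
    dekadal (10-day) raster time series. Implements the standardized anomaly
    indicators it combines (SPI-1/SPI-3 via gamma standardization, soil
    moisture anomaly, FAPAR anomaly), dynamic dekadal snow masks from daily
    NDSI fields, static crop/growing-season masks from crop fraction and
    phenology rasters, the stateful decision-table classifier with version
    switching (v2/v3/v4), a fully synthetic scene generator with injectable
    drought events, plain-text raster I/O and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
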