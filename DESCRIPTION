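Package: ferrolux
Title: Chlorophyll-Normalized Fluorescence Diagnostics of Ocean Iron
    Limitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing phytoplankton iron limitation from
    sun-induced chlorophyll fluorescence. Computes fluorescence line
    height (FLH) and OC3 chlorophyll from above-water hyperspectral
    radiometry, chlorophyll-normalized fluorescence yields from ship and
    satellite records (including solar-zenith denormalization of nFLH),
    blank-corrected active fluorometry and bioassay growth-rate
    reductions, ranged-major-axis (type II) regression of regional
    anomaly time series against sea surface temperature, and an
    emergent-constraint comparison of observed versus modelled
    Fe-limitation sensitivity. A synthetic-data generator emulates the
    cruise radiometry, satellite fields, model limitation terms and
    bioassay tables so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
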