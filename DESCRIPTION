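Package: effortseas
Title: Seasonality Analysis of Gridded Industrial Fishing Effort
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns daily per-vessel fishing records (as produced by
    AIS-based fishing detection) into gridded vessel-day effort at 0.5, 1.0
    and 4.0 degree resolution and characterizes its seasonality:
    gear-stratified global monthly effort series and their relative
    variation, an implied winter-holiday day estimator, a per-cell
    seasonality index of the 12-month climatology, principal-component
    peak-month maps with zero-year and explained-variance filters,
    effort-weighted variability profiles by distance to the nearest port,
    and exclusive-economic-zone masking. A synthetic AIS-like generator
    (parametric seasonal fields with moratorium and holiday forcing, and a
    bioeconomic fleet-dynamics simulator) provides data with fully known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
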