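Package: spreadday
Title: Fire-Weather Thresholds for Wildfire Spread Days
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies Canadian Fire Weather Index (FWI) System thresholds
    for wildfire "spread days" from daily fire growth records.  Implements
    the full pipeline: the six daily FWI System indices from noon weather,
    daily fire-growth delineation inside a final perimeter from dated
    satellite hotspots, pairing of growth footprints with downscaled
    fire-weather grids (regression kriging on elevation), threshold
    estimation as the 50% crossing of smoothed cumulative area-burned
    curves with year-resampling, percentile analysis of the thresholds, and
    potential versus realized spread-day (PSD/RSD) accounting.  A synthetic
    data generator with known ground-truth thresholds makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
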