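Package: nadirchm
Title: Crop Height Models and Plant Heights from Nadir Time-of-Flight
    Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives continuous raster crop height models (CHM) and
    individual plant heights directly from single-campaign point clouds
    captured by a nadir-mounted low-cost time-of-flight depth camera,
    without a prior bare-terrain survey. Implements the full processing
    chain (field-of-view clipping, statistical outlier removal, tie-point
    rigid registration, per-cell extreme rasterization of DSM/DTM/CHM,
    border-cell trimming), individual plant height extraction from local
    maxima or known positions, and a robust accuracy-assessment suite
    including the normalized median absolute deviation (NMAD) and
    quantile-based error measures. A built-in virtual maize field and
    virtual depth-camera/laser-scanner renderers provide ground-truth
    scenes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
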