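Package: camflor
Title: Linear Reflectance Recovery from Visible and Ultraviolet Digital Camera Images of Flowers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiometric calibration toolkit for quantifying floral colour signals
    with consumer-level digital cameras in the visible and ultraviolet bands.
    Models channel spectral sensitivities as one- or two-term Gaussian sums,
    fits exponential and biexponential camera transfer functions from grey-ramp
    characterisation series, inverts them into 8-bit linearisation look-up
    tables with bootstrap uncertainty, standardises exposure against in-frame
    achromatic reflectance standards, and recovers per-pixel reflectance maps.
    Includes CIE daylight-series illuminant synthesis, a forward camera model
    for rendering synthetic ground-truth scenes (including UV bullseye floral
    patterns), and point/grid sampling statistics for comparing camera-derived
    reflectance with spectrophotometer-predicted channel responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    pracma,
    withr,
    yaml,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
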