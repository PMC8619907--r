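Package: uwcal
Title: Optical Calibration Tools for Rotating Underwater Video Landers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibration analysis for unbaited rotating underwater video
    systems: field-of-view estimation from grid-target span measurements,
    air/water field-of-view conversion through flat-port refraction, a
    one-coefficient grid-distortion model with least-squares fitting and
    point/image undistortion, per-channel exponential colour-attenuation
    fitting from colour-chart series, a synthetic pool calibration-target
    renderer with ground truth, and a discrete-event simulator of the
    lander's recording protocol with its metadata log.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
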