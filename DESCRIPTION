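Package: pupilorbit
Title: Pupil Orbit Model Estimation for Eye-Gaze Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the ocular rotational center point (ORCP) and pupil
    orbit radius of an eye from elliptically projected pupil contours. The
    minor axis of every elliptically deformed pupil image points at the
    eye's rotational center, so the center is recovered as the least-squares
    intersection (singular-value-decomposition pseudo-inverse) of the
    minor-axis lines inside a RANSAC consensus loop. Includes an
    orthographic pupil-projection simulator for generating ideal and noise
    ellipse datasets, direct least-squares ellipse fitting from contour
    points, and a repeated-trial evaluation harness reporting accuracy and
    precision of the estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
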