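Package: fishmetry
Title: Dual-View Keypoint Morphometry for Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based morphometry of fish from two orthogonal camera views
    (lateral and dorsal). From labelled 2D keypoint skeletons plus a
    ruler-based pixel-to-metric calibration per view, computes seven
    phenotypic measurements (full length, body length, body height, body
    thickness, head length, tail-handle height and tail-handle width) via
    planar vector geometry and a dual-view 3D length-reconstruction
    transform that corrects for body curvature in water. Includes RMSE, MAE
    and mean-relative-error evaluation against manual measurements, a
    synthetic 3D fish generator with known ground-truth phenotypes for
    validation, and a compact stacked-hourglass heatmap regressor for
    keypoint detection on rasterised views.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
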