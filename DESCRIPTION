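Package: spinetrace
Title: Automated Cobb Angle Measurement from Spine Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies scoliosis from binary spine segmentation masks of
    anteroposterior radiographs. Reconstructs the spinal midline by
    grid-row midpoint extraction and cubic spline interpolation, detects
    curve apexes and the most tilted vertebrae, computes Cobb angles and
    a clinical severity class, and exports structured CSV reports and
    annotated overlay images. Also provides pixel-overlap segmentation
    evaluation metrics (IoU, Dice, average precision over IoU thresholds,
    over- and under-segmentation), method-agreement statistics for paired
    Cobb measurements (Bland-Altman limits of agreement, ICC(2,1) with
    confidence interval, median and mean absolute differences), and a
    synthetic spine-mask generator with analytic ground-truth curvature
    for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
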