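Package: phantomqa
Title: Geometric-Accuracy Quality Assurance for Preclinical MRI with a
    Structural Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phantom-based geometric quality assurance of small-bore
    (preclinical) MRI scanners. Provides a parametric model of a small cuboid
    structural phantom with a central frustum-shaped compartment, a scan
    simulator producing T2-weighted multi-slice stacks and high-resolution
    CT-like volumes with configurable gradient scaling errors, smooth nonlinear
    distortion, partial volume, bias field and Rician noise, sub-pixel
    opposing-edge dimension measurement, compartment volumetry by thresholded
    pixel counting, CT threshold calibration against caliper dimensions,
    per-direction linear scaling errors and volumetric errors with the
    predicted volumetric error implied by linear scaling, rank-based and
    agreement statistics (Mann-Whitney U, Bland-Altman, Dice), and 2D
    rigid plus free-form (B-spline) registration yielding per-pixel
    displacement-magnitude maps. Includes an orchestration layer that runs
    complete between-scanner and longitudinal within-scanner QA studies on
    simulated or user-supplied data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    EBImage,
    RNifti,
    yaml,
    jsonlite,
    readxl
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
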