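Package: fundusfd
Title: Stability of Retinal Vasculature Fractal Dimension Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the fractal dimension of retinal blood vessel networks
    (box, information and correlation dimensions from box-counting scans) and
    quantifies how stable those measurements are under the perturbations that
    occur in practice: different observers, segmentation methods, analysis
    regions, binarization thresholds and cameras. Includes a multiscale
    Hessian vesselness filter, optic-disc and fovea geometry estimation,
    seeded synthetic vascular phantoms and analytic fractal fixtures with
    exactly known dimension, and a six-study reliability harness reporting
    relative errors, relative standard deviations, repeatability, pairwise
    ANOVA comparisons and Pearson association tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
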