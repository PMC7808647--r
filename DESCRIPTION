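Package: smallfovmar
Title: Metal Artifact Reduction for Small Field-of-View Fan-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sinogram-inpainting metal artifact reduction (MAR) for fan-beam
    CT when the scan field of view is smaller than the object, so that
    projections are truncated and metal objects may sit outside the
    reconstructable region.  Implements truncation correction by symmetric
    mirroring with a cosine taper, re-synthesis of a consistent sinogram by
    forward projection of the truncation-corrected image, and linear (LMAR)
    and normalized (NMAR) sinogram inpainting on either the measured or the
    synthesized sinogram.  Ships a flat-detector fan-beam projector and
    filtered-backprojection reconstructor, a polychromatic X-ray measurement
    simulator with Poisson noise and beam hardening, synthetic phantom
    generators with known ground truth, and NMSE/SSIM image-quality metrics
    with an experiment harness for paired pipeline comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
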