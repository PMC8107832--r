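Package: nucscatter
Title: Stochastic Nuclear Refractive-Index Models and Azimuth-Resolved
    Light-Scattering Texture Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds stochastically inhomogeneous three-dimensional nuclear
    refractive-index models with Gaussian spatial correlation (spectral and
    turning-bands Gaussian random field generators), computes their
    azimuth-resolved far-field scattering patterns I(theta, phi) with a
    first-Born FFT solver (with a Mie-series oracle for homogeneous spheres
    and a pluggable solver-backend contract), and extracts gray-level
    co-occurrence (Haralick) contrast features -- azimuthal contrast, polar
    contrast and their ratio -- over small-angle, side and high-angle ranges.
    Also provides the companion image-analysis routine that estimates the
    chromatin correlation length of stained-nucleus images from row/column
    autocorrelations with constrained Gaussian fits, a synthetic-image
    generator with known ground truth, and parameter-sweep orchestration
    with replicate aggregation and monotone-trend checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
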