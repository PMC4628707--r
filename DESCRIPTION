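Package: vtseg
Title: Centerline-Based Segmentation of Tubular Anatomy with Greedy Active Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiautomatic segmentation of elongated, curved anatomical cavities
    (designed for the vocal tract in volumetric MRI) from a user-defined
    centerline. A piecewise-cubic spline is threaded through anatomical
    landmarks, the image stack is resampled into cross sections orthogonal to
    the curve using Frenet frames, and each cross section is segmented with a
    greedy active contour whose energy couples adjacent slices. Outputs include
    the cross-sectional area function, compartment volumes, world-space contour
    stacks, and a lofted triangle surface mesh. Includes edge-preserving
    anisotropic diffusion preprocessing, NIfTI and multi-page TIFF stack I/O,
    a synthetic curved-tube phantom generator with analytic ground truth, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
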