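Package: qpli
Title: Quantitative Polarized-Light Imaging Reconstruction and Virtual Staining
Version: 0.1.0
Authors@R: person("QPLI", "Maintainers", email = "maintainers@qpli.dev", role = c("aut", "cre"))
Description: Joint reconstruction of phase, retardance, slow-axis orientation,
    brightfield and degree of polarization from five-state polarization-resolved
    z-stacks acquired with a liquid-crystal universal polarizer. Implements the
    Stokes/Mueller instrument-matrix forward model and its least-squares
    inversion, two-round polynomial background correction, weak-object
    transfer-function (WOTF) phase deconvolution with Tikhonov and total
    variation regularization, a synthetic phantom simulator that renders
    five-channel acquisitions through the same forward physics, and a
    from-scratch multi-channel 2D/2.5D/3D residual U-Net stack for
    label-free to fluorescence image translation, with per-dataset
    median/interquartile-range normalization, tiled training, stitched
    inference, and Pearson/SSIM volumetric evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
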