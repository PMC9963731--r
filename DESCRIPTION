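Package: hsmisr
Title: Multi-Frame Super-Resolution for Hyperspectral Microscopy Cubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-image super-resolution (MISR) of hyperspectral
    cubes acquired with push-broom scanners, aimed at histological microscopy.
    Provides white/dark reference calibration of raw captures, an observation
    -model simulator that degrades a high-resolution cube into labelled
    sub-pixel-shifted low-resolution sequences, global quarter-pixel motion
    estimation by full-search block matching on a PCA-synthesized band,
    shift-and-add reconstruction onto an upscaled grid with bilinear hole
    filling, and SSIM/PSNR/SAM quality evaluation against a bilinear
    interpolation baseline. Cubes are read and written in ENVI and HDF5
    formats; MATLAB v5 files can be imported.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    rhdf5,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
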