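Package: nucperi
Title: Subnuclear Locus Positioning and Mobility from Fluorescence Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the subnuclear position and mobility of a
    fluorescently tagged chromosomal locus from two-channel 3D confocal
    z-stacks, as used in budding-yeast replication-origin localization
    assays. Segments the nuclear envelope (e.g. Nup49-GFP) by radial ridge
    detection and robust ellipsoid fitting, localizes the locus focus
    (e.g. TetR-Tomato, LacI-GFP) by multiscale blob detection with
    subvoxel refinement, and measures the shortest focus-to-periphery
    distance in 3D or in a 2D middle-section mode. Time-lapse stacks are
    assembled into drift-corrected trajectories for mean-squared
    displacement analysis, radius-of-constraint and explored-volume
    estimation, and group comparison by z-test and two-tailed
    Mann-Whitney test. A seedable synthetic-microscopy and
    confined-diffusion simulator provides ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
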