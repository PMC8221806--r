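Package: qpicell
Title: Quantitative Phase Imaging of Dry-Mass Density in Rod-Shaped Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for absolute dry-mass density measurement of rod-shaped
    cells (e.g. fission yeast) from bright-field defocus z-stacks. Implements
    transport-of-intensity phase retrieval, calibration-standard scaling to
    mg/mL, watershed segmentation with sub-pixel contours, centerline
    skeletonization and volume-of-revolution morphometry with spherical-cap
    poles, time-lapse lineage tracking, cell-cycle alignment, growth-law model
    selection, and the companion two-fluid suspended-microchannel-resonator
    buoyant-density inversion. Ships a forward optical simulator (spherocylinder
    phantoms, angular-spectrum defocus) so the full inverse pipeline is testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
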