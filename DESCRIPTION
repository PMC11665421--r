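Package: unjamr
Title: Quantitative Analysis of 3D Spheroid Invasion and Cell Unjamming
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify 3D spheroid invasion assays from bright-field
    time-lapse microscopy: gradient-based spheroid segmentation with effective
    circular radius tracking, invasion onset and power-law expansion-rate
    estimation, polar-coordinate protrusion detection with
    solid/liquid/gas unjamming-phase classification, hydrogel confinement
    characterization (bubble-method pore size from confocal reflectance
    stacks, void fraction, Darcy permeability from dye-front tracking), and
    assembly of condition-level heatmaps and unjamming phase diagrams. A
    seeded synthetic-data module generates ground-truthed image stacks,
    fiber networks and dye fronts so the whole pipeline is testable without
    raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
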