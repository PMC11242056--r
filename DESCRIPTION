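Package: callusim
Title: Mechano-Regulated Fracture-Healing Simulation on Voxel Digital Twins
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Desk-scale digital twin of a fixed long-bone shaft fracture.
    Generates idealized voxel models of a nailed tibial or femoral
    diaphysis with a fracture gap and periosteal healing domain, solves
    small-strain linear elasticity on the voxel mesh every simulated day,
    and evolves the tissue composition (lamellar bone, woven bone,
    cartilage, fibrous tissue) and vascularity with fuzzy mechano-regulation
    rules in the Claes-Heigele tradition.  Cortical bridging is detected per
    anatomical quadrant by a path search over lamellar bone, and a case is
    classified as union when at least three quadrants bridge within the
    simulated horizon.  Includes weight-bearing sweeps, simulated
    radiographic projections, VTK export, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
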