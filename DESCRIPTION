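Package: tissuemodel
Title: Structural Tissue Models and Morphogen Transport Simulation from
    Segmented 2D Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a cell-resolved structural model of a two-dimensional
    tissue from a preprocessed (segmented) microscopy image: cells and wall
    segments are identified as connected components, indexed, and measured
    (area, perimeter, centroid, characteristic ellipse, wall length and
    width), and each shared wall is classified as lying on the top, bottom,
    left or right side of a cell by a rule-based orientation algorithm with
    neighbour-based resolution and manual correction. The structural model is
    then embedded into a system of ordinary differential equations describing
    morphogen production, turnover, passive (Fick) transport and active
    carrier-mediated polar transport between adjacent cells, integrated with
    a stiff variable-order solver to steady state, and the resulting per-cell
    concentrations are rendered back onto the cell layout. Includes a
    synthetic layout generator (rectangular, jittered and root-tip-like
    tissues) with exhaustive ground truth for validation, and a demonstration
    polar-transport model that self-organizes an interior morphogen maximum.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    grDevices,
    igraph,
    Matrix,
    methods,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
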