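Package: capfate
Title: Quantifying the Fate of Obstructed Cortical Capillaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cortical capillary obstruction and its
    long-term consequences from two-photon imaging data: red blood cell
    velocimetry from line scans, full-width-at-half-maximum lumen diameters
    and laminar RBC flux; an automated capillary census from fluorescence
    stacks (maximum projection, Triangle auto-thresholding, median
    despeckling, topological skeletonization, and conversion of vascular
    volume to capillary counts); longitudinal accounting of obstruction
    fates (recanalization by washout or angiophagy versus pruning) and
    obstruction-rate estimation; a branch-order-structured stochastic model
    of capillary rarefaction over months; and vascular immunosignal coverage
    scoring with population classification. A synthetic-data module
    generates tubular vessel phantoms, line-scan images, fate tables, and
    two-channel projections with known ground truth so every stage is
    testable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
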