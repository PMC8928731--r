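Package: beadmetrics
Title: Morphometry, Permeability and Fibrotic-Overgrowth Scoring for
    Alginate Microbead Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of alginate microbead
    microscopy: seeded synthetic brightfield and fluorescence scene
    generation with ground truth, circular Hough-transform bead detection
    with sub-pixel refinement, size-distribution morphometry and
    encapsulated-spheroid counting, FITC-dextran permeability scoring
    with two-anchor normalization, ray-based pericapsular fibrotic
    overgrowth (PFO) coverage grading, and Welch's t-test with
    noncentral-t power and sample-size calculations. Includes an
    end-to-end seeded pipeline and a ground-truth evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
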