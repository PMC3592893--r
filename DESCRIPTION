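Package: yeastvote
Title: Multi-Threshold Watershed Voting Segmentation and Backward
    Tracking of Budding Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments and tracks budding yeast cells in phase-contrast
    time-lapse movies by summing watershed segmentations over all 256
    intensity thresholds (a "plurality vote"), refining the composite
    score with movement and boundary penalties, and propagating each
    cell's mask backward in time from a seeded final frame. Includes
    seeding utilities, morphology and nuclear-fluorescence feature
    extraction with reference-channel focus correction, a synthetic
    colony-movie generator with ground truth, and an evaluation module
    with a proper/minor/major segmentation error taxonomy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: methods, stats, utils, tools, Rcpp, tiff, yaml, jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
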