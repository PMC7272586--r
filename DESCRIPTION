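Package: confinometry
Title: Quantification of Fibrous Matrix Structure, Cell Invasion and
    AFM Elasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for 3D cell-invasion studies in fibrous
    extracellular matrices. Provides sphere-fitting pore-size estimation
    with residual analysis steps and medial-axis fiber-thickness
    estimation for binarized collagen and actin networks (2D and 3D),
    nucleus detection and invasion-depth classification for gridded
    epifluorescence z-stacks, nuclear shape morphometry, Hertz
    contact-model fitting of AFM force-distance curves under matrix,
    cytoskeleton and nucleus probing protocols with residual-RMS curve
    filtering, and Mann-Whitney condition comparisons. Seeded synthetic
    generators produce fibrous networks, nucleus stacks and force curves
    with ground truth attached, so every stage is testable without raw
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
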