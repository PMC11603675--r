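Package: palatemap
Title: 3D Palatal Bone Thickness Cartography for Orthodontic Mini-Implant Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying palatal bone supply for orthodontic
    mini-implant (temporary anchorage device) planning from CBCT-like
    volumes. Provides Hounsfield-threshold segmentation of bone and teeth
    with iso-surface extraction, an anatomical coordinate frame built from
    nasal-spine, molar-fissure and occlusal landmarks, partition of the
    palatal vault into six paramedian regions of interest, per-vertex
    oral-to-nasal-floor thickness maps with area (AA), mean distance (MD)
    and integrated-distance volume (Vol = AA x MD) summaries, angulated
    insertion-corridor probing (0-30 degrees) with tooth-root conflict
    detection, and a statistical layer with random-intercept linear mixed
    models, exact nonparametric rank tests and age-trend smoothing.
    Synthetic phantoms with analytic ground truth (slabs, spherical
    shells, thickness-gradient vaults with incisor roots and a nerve-canal
    void, simulated patient cohorts) make every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
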