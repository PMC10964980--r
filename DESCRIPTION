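Package: ilamr
Title: Isochronal Late Activation Mapping for Ventricular Tachycardia Substrate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for automated isochronal late activation mapping (ILAM) of
    ventricular substrate from electroanatomical mapping data, with an emphasis
    on repaired tetralogy of Fallot. Provides a synthetic electroanatomical map
    generator (labelled right-ventricular-like surface meshes, first-arrival
    activation simulation with spatially varying conduction velocity, multi-
    deflection bipolar electrogram synthesis), last-deflection local activation
    time annotation, eight-isochrone map construction, deceleration-zone
    detection by isochronal crowding, anatomical-isthmus delineation with
    conduction-velocity estimation and slow-conduction classification, and the
    validation statistics (confusion metrics with F-score, ROC/AUC, Spearman
    correlation, rank-sum and Fisher tests) used to benchmark deceleration zones
    against slow-conduction isthmuses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
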