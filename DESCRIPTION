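Package: scartools
Title: Quantitative Analysis of Cardiac Scar Electrophysiology and Ultrastructure
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two quantitative pipelines used in the study of healed
    myocardial scar tissue. The passive-spread pipeline converts optical-mapping
    voltage movies into maximal-amplitude maps, partitions a region of interest
    into equal-width amplitude bins, measures edge-referenced radial distances
    from a stimulating electrode, and estimates a tissue decay (space) constant
    by single-exponential least squares. The morphometrics pipeline quantifies
    per-cell volumes, surface areas, intercellular contact interfaces and the
    cell-contact network from labeled 3D electron-microscopy voxel volumes with
    anisotropic voxel pitch. A synthetic-data module generates amplitude maps,
    voltage movies and packed multi-cell label volumes with known ground truth,
    so every stage of both pipelines can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
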