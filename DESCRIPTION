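Package: beamrisk
Title: Geometry-Based Beam-Angle Risk Maps for Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ray-traced water-equivalent path length (WEPL) motion-sensitivity
    maps and geometric organ-exposure maps over the gantry-couch angle space
    for proton beam-angle selection. Converts 4DCT Hounsfield-unit volumes to
    relative stopping power, traces parallel proton ray bundles to the distal
    edge of the target with exact Siddon-style voxel traversal, computes
    per-orientation delta-WEPL (motion sensitivity) and percentage irradiated
    volume (organ exposure) metrics, combines them into Z-score normalised,
    weighted and constrained unified risk maps, and selects beam sets under a
    minimum central-angle separation. Includes a synthetic 4D thorax phantom
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
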