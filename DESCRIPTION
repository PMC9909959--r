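Package: ctoam
Title: Computed Tomography Osteoabsorptiometry of Subchondral Bone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computed tomography osteoabsorptiometry (CTOAM) of the
    knee: Hounsfield-unit interval segmentation of subchondral bone into the
    twelve-bin density scheme, extraction of the bone tissue of interest
    between the articular surface and the epiphyseal line, maximum-intensity
    projection of subchondral density onto the articular surface, nine-region
    high-density-area frequency analysis, distribution-pattern classification,
    per-bin bone-tissue volume percentages, and normality-gated two-group
    statistics. Includes a synthetic knee-phantom generator with voxel-exact
    ground truth so the full pipeline can be exercised and validated without
    clinical scans, plus NIfTI and basic DICOM series input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    yaml,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
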