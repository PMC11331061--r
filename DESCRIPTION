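Package: pamcal
Title: Precision Calibration and Biodiversity Summaries for Acoustic
    Vocalization Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing for large-scale passive acoustic monitoring of
    bird vocalizations. Given confidence-scored detections from an automated
    vocalization classifier, the package samples detections for expert
    validation, estimates per-species precision on a threshold grid from the
    labeled subsample, calibrates per-species and per-dataset classification
    thresholds (lowest threshold reaching a target precision), filters out
    unreliable detections, and computes biodiversity summaries: diel vocal
    activity profiles, habitat-stratified daily vocalization rates, migration
    fronts from detection latitudes, and clustered species-by-time occurrence
    matrices. A synthetic detection-stream generator with known ground truth
    (Poisson event streams, von Mises diel kernels, Beta-distributed
    confidence scores, residency windows and moving latitudinal presence
    bands) makes the whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
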