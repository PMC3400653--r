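Package: fluotrack
Title: Two-Camera Fluorescence Video Tracking of Small Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects fluorescent animals in dark-field video by
    running-Gaussian background subtraction with selective update, cleans
    binary change masks by 3x3 morphological opening, extracts 8-connected
    silhouette components with size filtering and centroids, quantifies
    per-animal fluorescence with a four-bin intensity histogram per colour
    channel, reconstructs 3D trajectories from two calibrated views by
    midpoint triangulation of back-projected rays, and summarises motion
    (speed, heading-change frequency) and reporter-induction time courses
    (per-minute averaging, LOESS smoothing, onset detection). Includes a
    synthetic two-view scene generator with exported ground truth so the
    whole pipeline is testable without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
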