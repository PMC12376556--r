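Package: rmtrack
Title: Trajectory Analysis of Neutrophil Reverse Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify reverse migration of neutrophils from 2D
    cell-track tables exported by image trackers. Aligns coordinates to a
    circular injury spheroid, computes per-step distances and velocities,
    partitions each track into approach / within-spheroid / reverse segments
    by a radius-contact rule with a last-exit convention, labels
    reverse-migrated cells, computes displacement-over-distance track
    straightness, and renders cell-location heatmaps by 2D Gaussian kernel
    density estimation with Scott's-rule bandwidths. Includes a
    ground-truth-labeled biased persistent random-walk simulator of
    neutrophil tracks in a microphysiological sterile-injury geometry, so
    the full pipeline is testable without imaging data, plus thin wrappers
    for the group-comparison statistics used in reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
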