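Package: collmigr
Title: Collective Cell Migration Metrics and Single-Cell Dispersion from
    Nuclear Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies collective cell migration in spheroid outgrowth
    assays from per-nucleus tracking tables such as TrackMate spot-statistics
    exports. Computes per-cell and population migration metrics (accumulated
    and Euclidean distances, mean/median and instantaneous speeds,
    directionality ratios, polar direction distributions, speed-binned
    directionality, and a nematic alignment order parameter for contact
    guidance on aligned fiber substrates), classifies detached "single" cells
    per frame by a nearest-neighbour distance threshold, produces dispersion
    time series and deterministic overlay renderings, and includes an
    agent-based synthetic spheroid-outgrowth simulator (biased persistent
    random walk with axial von Mises contact-guidance bias and stochastic
    detachment) so every pipeline stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
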