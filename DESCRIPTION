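Package: ddplexr
Title: Analysis of Amplitude-Multiplexed Droplet Digital PCR
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for amplitude-coded multiplex droplet digital PCR (ddPCR)
    on two-channel droplet readers. Reads raw per-droplet fluorescence
    exports, automatically places cluster separation lines (three per
    channel for a 4-plex, yielding the 16-cluster grid), classifies
    droplets, and performs absolute quantification by Poisson partition
    statistics with confidence intervals. Includes the method-performance
    rule set used in GMO quantification (absolute limits of detection and
    quantification, repeatability, trueness, proficiency z-scores,
    mass-fraction/copy-ratio conversion, false-positive assessment of
    "rain" droplets), a synthetic droplet simulator with per-droplet ground
    truth, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
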