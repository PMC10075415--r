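Package: beeloop
Title: Persistent Turning Walker Simulation of Central-Place Foraging Bees
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates exploratory flights of central-place foraging bees as
    a constant-speed persistent turning walker whose angular speed follows an
    Ornstein-Uhlenbeck process, with an intermittent homing term that returns
    the bee to its nest. Provides nest-to-nest loop segmentation and the four
    loop observables used for calibration, simulation-based grid-search
    calibration matching full observable distributions, random flower fields
    with visual perception geometry, and flower-discovery experiments that
    quantify the perceptual masking effect, including discovery-probability
    profiles, discovery radii, colony-level distinct-flower counts and mean
    squared displacement estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
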