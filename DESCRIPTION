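Package: mutet
Title: Prediction and Decomposition of Unfused Tetanic Contractions of Motor Units
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the force output of single motor units during unfused
    tetanic contractions. A bell-shaped six-parameter analytical curve
    represents each twitch-like contraction; successive contractions within a
    tetanus are predicted from the first-twitch parameters, the maximal fused
    tetanus force and an arbitrary stimulation pattern, via a motor-unit
    specific angle relating contraction amplitude to the force level at which
    the contraction starts. Includes sequential decomposition of recorded
    tetanic curves into twitch-like contractions, the FitCo and AreaCo
    similarity coefficients, sensitivity analysis and power-model calibration
    of the angle-ratio relationship, a synthetic motor-unit and stimulation
    pattern generator for the slow, fast fatigue-resistant and fast fatigable
    unit types, and text-file input/output with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
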