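Package: kpgrowth
Title: Geomagnetic Kp-Gradient Analysis of Moss Growth Response to Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the geomagnetic Kp index modulates the
    temperature growth response of peat moss from interval-sampled field
    monitoring. Reconstructs daily growth-rate patterns from plot-level
    sampling intervals, removes seasonal trends (per-season quadratic for
    growth, annual harmonic for temperature), computes Pearson correlations
    between growth and day-prior temperature in a sliding window along the
    sorted Kp gradient, detects the Kp interval with an enhanced temperature
    response, calibrates it against a permutation null envelope, and profiles
    the response against diurnal temperature at the eight 3-hourly synoptic
    times. Includes a synthetic campaign generator with known ground-truth
    coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
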