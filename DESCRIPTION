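Package: gliderpsych
Title: Maximum-Entropy Glider Textures and Ideal-Observer Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for visual psychophysics with binary textures defined by
    local multipoint (glider) correlations. Generates maximum-entropy binary
    textures at controlled statistic intensities, measures empirical glider
    statistics, implements a Bayesian ideal-observer model of
    texture-versus-noise discrimination with truncated-Gaussian percepts,
    fits the resulting psychometric function to two-alternative forced-choice
    data by maximum likelihood, simulates the behavioral experiment
    (including the adaptive staircase used in training), and tests the
    agreement between sensitivity vectors with a Monte Carlo cosine-similarity
    ("degree of correspondence") null test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
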