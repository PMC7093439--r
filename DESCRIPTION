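Package: workloopr
Title: Work-Loop Analysis of Isolated Cardiac Muscle Contractility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of cardiac work-loop experiments on isolated papillary
    muscle preparations: phase-decomposed force-length loop integration, net
    work and mass-normalised net power output, length-optimisation and
    muscle-geometry calculations, stabilisation-normalised drug time-courses
    with a stability exclusion filter, repeated-measures statistics, and
    inotrope classification. Includes a phenomenological Hill-type twitch
    simulator that generates the force/length/stimulus traces a work-loop rig
    would record, with calibrated drug-effect presets for six reference
    inotropes, so the full pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    yaml,
    ggplot2,
    rlang
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
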