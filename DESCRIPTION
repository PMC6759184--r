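Package: clockloops
Title: Interlocked Circadian Feedback Loops: Surrogate Movies, Rhythm
    Analysis and Coupled-Oscillator Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying transient dissociation between the Per and
    Bmal-Rev circadian feedback loops. Generates surrogate dual-reporter
    time-lapse movies under competing single-cell versus two-population null
    hypotheses; analyses rhythms by Hodrick-Prescott detrending, Lomb-Scargle
    periodograms, harmonic fits, acrophase tracking and bivariate kernel
    density cluster counting; and simulates three model classes of the
    interlocked loops: a two-oscillator phase model with analytic
    synchronisation theory, a pair of mean-field coupled Poincare
    amplitude-phase oscillators, and a three-gene delay-differential-equation
    circuit (Per, Bmal1, RevErb) with entrainment, jet-lag, light-pulse and
    phase-response-curve protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
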