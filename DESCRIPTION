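Package: chronobug
Title: Circadian Locomotor-Activity, Photoperiodism and Expression-Rhythm
    Analysis for Insect Chronobiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native analysis chain for insect chronobiology
    experiments: parsing Trikinetics-style activity-monitor files and light
    schedules expressed in Zeitgeber time, smoothed average-day activity
    profiles with onset/offset phase statistics, Lomb-Scargle periodogram
    estimation of the free-running period in constant conditions,
    JTK_CYCLE-style nonparametric rhythmicity testing, circular statistics
    (Rayleigh test, two-sample Watson's U2), efficiency-corrected qPCR
    relative quantification, immunostaining densitometry, and photoperiodic
    response-curve fitting with critical-day-length estimation.  A synthetic
    cohort generator (Poisson activity agents with clock-driven and
    masking-driven components, binomial diapause responses, Cq tables, and
    stained-brain image fixtures) provides reproducible inputs with the
    statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
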