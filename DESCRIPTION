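Package: circafly
Title: Circadian Behavior and Molecular Rhythm Analysis for Drosophila
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the quantitative workflow of a
    Drosophila circadian RNAi screen: chi-squared (Sokolove-Bushell)
    periodogram estimation of free-running period and rhythmicity calling
    from locomotor activity, eduction profiles and peak-phase extraction,
    light-pulse phase-shift and temperature-cycle phase quantification,
    morning/evening anticipation scores, exponentially damped cosinor
    fitting of luciferase reporter rhythms, batch-stratified two-standard-
    deviation screen hit-calling, and 2^-ddCt relative expression from qPCR
    Ct tables.  Includes readers for Trikinetics DAM monitor files and a
    tidy CSV dialect, and synthetic-data generators with known ground truth
    so every analysis stage has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
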