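Package: aeropollen
Title: Airborne Pollen Season Statistics, Calendars and Wind Source-Receptor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing airborne pollen monitoring data from volumetric
    (Hirst-type) traps: conversion of raw slide counts to atmospheric
    concentrations, the Annual Pollen Integral (APIn), Main Pollen Season
    delimitation by the 90 percent (5-95 percent cumulative) method,
    multi-year pollen calendars with flowering-period classification,
    diurnal (hourly) concentration profiles, Spearman screening of
    pollen-meteorology associations restricted to the pollen season, and
    estimation of the geographical origin of pollen from wind records by
    non-parametric wind regression and the Sustained Wind Incidence Method
    (SWIM), including the single-pass Yamartino wind-direction standard
    deviation. A synthetic-data module generates pollen, meteorology and
    wind fixtures with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    nortest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
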