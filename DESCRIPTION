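Package: fetalqeeg
Title: Quantitative EEG Response of the Fetal Brain to Repeated Umbilical
    Cord Occlusions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and quantitative analysis of fetal EEG under a
    protocol of repeated umbilical cord occlusions of increasing frequency.
    Provides a synthetic generator of multichannel fetal EEG, haemodynamic
    and gasometric signals under the staged occlusion protocol (stability
    hour followed by mild/moderate/severe occlusion phases and a pH stop
    rule), three quantitative EEG features computed on 2-s bipolar
    intervals (minimum amplitude index on the 2-20 Hz envelope, burst
    suppression ratio, 95% spectral edge frequency), windowed median
    aggregation into phase summary tables, and the nonparametric
    statistical stage (Friedman repeated-measures test, pairwise Wilcoxon
    post-hoc, Spearman correlations between qEEG and physiological
    markers). EEG is read and written as EDF; physiology, schedules and
    reports as delimited text and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
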