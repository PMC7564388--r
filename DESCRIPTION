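Package: vigistab
Title: EEG Vigilance Staging and Arousal Stability Scoring
Version: 0.1.0
Authors@R:
    person("Jonas", "Brandt", email = "jonas.brandt@posteo.net",
           role = c("aut", "cre"))
Description: Tools to quantify central nervous system arousal regulation from
    20-minute eyes-closed resting electroencephalography (EEG). Classifies
    every 1-second EEG segment into one of seven vigilance stages (0, A1, A2,
    A3, B1, B2/3, C) from spectral band power, its scalp topography, slow
    horizontal eye movements, and sleep graphoelements (spindles,
    K-complexes); condenses a 1200-segment stage sequence into a 1-14 Arousal
    Stability Score; and dichotomizes participants into hyperaroused versus
    non-hyperaroused arousal regulation at a cutoff of 13. Includes a
    stage-faithful synthetic EEG and cohort generator, EDF and BrainVision
    readers and writers, the biostatistics layer used in arousal-regulation
    group comparisons (one- and two-way ANOVA with partial eta squared,
    Levene's test, Pearson chi-squared, tie-corrected Mann-Whitney U, binary
    screening metrics), and a reproducible end-to-end pipeline with a command
    line interface.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
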