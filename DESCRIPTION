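Package: painlep
Title: Inter-Stimulus EEG Correlates of the Laser-Evoked Potential-Pain
    Relationship and Individualized Cross-Individual Pain Prediction
Version: 0.1.0
Authors@R:
    person("painlep", "developers", email = "painlep@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how ongoing inter-stimulus EEG (isEEG)
    modulates the per-individual linear relationship between laser-evoked
    potential (LEP) N2-P2 amplitude and fast-pain ratings. Provides a
    seeded multi-subject synthetic EEG generator emulating a laser-pain
    experiment (1 kHz sampling, 10-15 s inter-stimulus intervals, 12-15
    energy levels with 10 pulses each), minimum-phase FIR band
    decomposition (delta to beta), isEEG magnitude (RMS) and temporal
    variability (normalized mean square successive difference, nMSSD)
    features with randomized sub-epoch resampling, per-subject LEP-pain
    model fitting with fast-pain trial selection, Bonferroni-corrected
    cross-individual correlation analysis, and a similarity-weighted
    individualized cross-individual pain prediction scheme evaluated by
    leave-one-individual-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
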