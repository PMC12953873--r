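Package: choirsync
Title: Respiration Phase Coupling and Ensemble Singing Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline relating interpersonal respiration phase
    synchronization to intonation and timing accuracy in vocal ensembles.
    Computes instantaneous phases of respiration traces by a Morlet
    continuous wavelet transform over the 0.025-0.40 Hz band and derives
    three pairwise phase-coupling indices (absolute coupling index,
    phase synchronization index, integrative coupling index) with
    aggregation to singer, voice, frequency-band and trial means. Turns
    annotated note events from unison singer pairs into mean absolute
    pitch error and mean onset error records via score matching, pitch
    drift removal and a gross-error filter cascade. Reproduces the
    statistical procedures of such studies: paired t-tests with Cohen's d
    on block-by-voice means, mixed-effects condition contrasts, and
    mixed-effects prediction of accuracy from coupling with
    likelihood-ratio model reduction. A coupled phase-oscillator
    simulator and a unison performance simulator provide fully synthetic
    study data sets with controllable coupling and accuracy, so the
    entire pipeline is testable without recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
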