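Package: saccmod
Title: Microsaccade Detection and Attention-Related Modulation of Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for covert spatial-attention experiments that
    record fixational eye movements together with extracellular spike trains.
    Detects microsaccades from 1 kHz eye-position traces with the classic
    two-dimensional velocity-threshold (elliptical criterion) algorithm,
    classifies them relative to the attention cue, bins and z-normalizes spike
    counts around task events, and implements the resampling controls needed
    to dissociate attention-related modulation from microsaccade generation:
    timing-matched subsampling with a matched no-microsaccade condition, and
    two-dimensional eye-position distribution matching. Statistical surfaces
    include balanced full-factorial fixed-effects ANOVA with Tukey-Kramer
    post hoc comparisons, rank tests, proportion tests, and Clopper-Pearson
    intervals. A synthetic-session generator produces complete task sessions
    (trials, eye traces, inhomogeneous-Poisson spike trains, behavioral
    outcomes) with known ground truth so that every analysis stage has a
    parameter-recovery test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
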