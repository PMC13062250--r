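Package: ssvepauth
Title: Single-Stimulus SSVEP Authentication with Filter-Bank Canonical
    Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Offline simulation and decoding toolkit for a brain-computer
    interface authentication paradigm in which a one-time code over the
    digits 1-3 is presented as a sequence of flicker frequencies and read
    back from occipital EEG. Provides a synthetic steady-state visual
    evoked potential (SSVEP) generator with pink-noise background, alpha
    rhythm and mains interference; Butterworth front-end and sub-band
    filter banks; filter-bank canonical correlation analysis (FBCCA)
    target identification with margin-threshold acceptance; a streaming
    blockwise decision engine; and trial, calibration and cohort
    orchestration with the standard accuracy and completion-time metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
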