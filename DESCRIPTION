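Package: mindstate
Title: EEG and Behavioral Signatures of Mind Blanking, Mind Wandering and
    On-Task States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising ongoing mind states (on-task, mind
    wandering, mind blanking) from EEG recorded during a sustained attention
    to response task (SART) with experience-sampling probes. Provides a
    synthetic SART-session generator with planted state signatures,
    probe-locked and stimulus-locked epoching with the 5-second trial
    labeling rule, spectral and complexity markers (normalized band power,
    sample entropy, compression complexity), connectivity metrics (weighted
    symbolic mutual information and phase-locking value, with ROI
    aggregation), single-trial ERP contrasts, temporal decoding of stimulus
    category with permutation chance levels, behavioral summaries (misses,
    false alarms, reaction times) per state, electrode-wise state contrasts
    with Benjamini-Hochberg correction, and a trial-by-trial mind-state
    classifier with block-grouped cross-validation and permutation null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    ranger,
    kernlab,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
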