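Package: streamsync
Title: Intracranial EEG Analysis of Visual-Stream Interactions During
    Memory-Guided Actions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for task-structured
    intracranial EEG: whitened filter-Hilbert band-power envelopes with
    sliding-window Wilcoxon/FDR active-channel detection, phase-locking
    value (PLV) connectivity with a permutation/cluster null and binomial
    band selection, and non-parametric spectral Granger causality via
    Wilson spectral-matrix factorization with net-GC directionality.
    Includes a synthetic session generator with known ground truth
    (task-period power modulations, Von Mises phase coupling, lagged
    directed coupling), EDF and BIDS-flavoured TSV input/output, bipolar
    re-referencing and artifact-epoch exclusion, and linear mixed-effects
    modelling of task-period by condition effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    lme4,
    lmerTest,
    emmeans
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
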