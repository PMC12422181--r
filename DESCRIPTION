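Package: neawake
Title: Norepinephrine Dynamics and Sound-Evoked Awakening Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studies of sound-evoked awakening and
    locus coeruleus norepinephrine signalling in mice. Implements fiber
    photometry preprocessing (isosbestic-referenced dF/F), event-locked
    epoching and response-window detection with one-sided many-to-one
    multiple-comparison correction, rule-based trial-outcome scoring and
    sleep-state transition curves, event-related spectral perturbation and
    EMG root-mean-square features with cluster-based permutation statistics,
    and a weighted Monte Carlo permutation framework for comparing the
    anatomical distributions of projection-defined neuron populations.
    A seeded synthetic-data generator emulates photometry, EEG/EMG,
    hypnogram, trial-schedule and cell-count data with known ground truth so
    every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mvtnorm,
    nnet,
    signal,
    yaml,
    jsonlite,
    multcomp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
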