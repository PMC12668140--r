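Package: somnostat
Title: Vigilance-State Classification and State-Dependent Neurophysiology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: An analysis stack for sleep and anesthesia neurophysiology in
    rodents. Classifies vigilance states (Wake, NREM, REM) from EEG, EMG and
    accelerometer recordings via multitaper spectral estimation, non-negative
    matrix factorization features and a feedforward neural-network classifier
    with leave-one-subject-out validation; quantifies state-dependent calcium
    transient rates and a state-preference index; models sleep-state dynamics
    as a bout-level Markov process; analyzes subthreshold membrane resonance
    from chirp (ZAP) stimuli and intrinsic properties from current steps; and
    provides the exact contingency, binomial and jackknife statistics these
    analyses use. A synthetic-data generator with known ground truth (Markov
    hypnograms, state-shaped EEG/EMG, calcium traces, linear resonant
    membranes) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    nnet,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
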