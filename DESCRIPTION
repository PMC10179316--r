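Package: vlpoCalcium
Title: Sleep-Wake Phenotyping of Preoptic Neurons from Miniscope Calcium Traces
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-cell calcium (GCaMP) fluorescence traces
    recorded across sleep-wake states. Implements trace conditioning (z-scoring,
    unit quality filtering, 10-s epoch downsampling aligned to a hypnogram),
    rule-based EEG/EMG sleep staging with NREM delta (2-4 Hz) power and its
    post-deprivation rebound, ratio-threshold classification of units into
    sleep-active, wake-active and state-indifferent phenotypes with subtype and
    strength grading, logistic-regression validation of classification rules,
    census tabulation across animals and genotypes, sleep-deprivation/recovery
    group analysis driven by a Process-S-like homeostatic pressure variable, and
    a nonparametric test battery (Friedman RM ANOVA on ranks with
    Student-Newman-Keuls post hoc, Wilcoxon signed rank, Mann-Whitney,
    Kruskal-Wallis with Dunn's method). A synthetic session generator (semi-Markov
    hypnograms, state-dependent Poisson spiking convolved with a GCaMP-like
    kernel, band-structured EEG/EMG) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    zoo,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
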