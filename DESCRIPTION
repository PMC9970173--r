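Package: microstatr
Title: EEG Microstate Cue-Reactivity Analysis with Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end EEG microstate analysis for cue-reactivity designs:
    global field power, polarity-invariant modified k-means clustering of
    GFP-peak topographies, Krzanowski-Lai selection of the number of
    microstate classes, permutation averaging of template maps across
    participants and conditions, back-fitting, and the classical segmentation
    parameters (duration, occurrence, contribution, global explained
    variance). A statistical layer provides paired contrasts, 2x4
    repeated-measures ANOVA with FDR-corrected post-hoc tests, Pearson
    correlations of condition differences, and percentile-bootstrap mediation
    of craving via posterior alpha power. A synthetic-cohort generator with
    known ground truth (semi-Markov microstate sequences, spatially
    correlated pink noise, posterior alpha injection, behavioural linkage)
    makes every stage testable against a recoverable truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    signal,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
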