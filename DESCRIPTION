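Package: mcimarkov
Title: Multistate Markov Models of Transitions Through Mild Cognitive Impairment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-time multistate Markov modelling of cognitive-state
    trajectories in longitudinal aging cohorts.  Classifies annual visits
    into normal cognition, test-based amnestic or mixed mild cognitive
    impairment (MCI), clinical-consensus MCI, dementia and death using
    age-adjusted 1.5 SD neuropsychological norms; enforces the
    quasi-absorbing structure of clinical MCI by deterministic
    back-transition reclassification; tabulates one-step transition
    matrices; and fits shared-random-effect polytomous logistic regression
    models of transition probabilities by maximum likelihood with adaptive
    Gauss-Hermite quadrature.  Includes a calibrated synthetic-cohort
    generator and parameter-recovery harness so the full pipeline can be
    exercised without access to restricted cohort data.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
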