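Package: seqwager
Title: Predictive and Reactive Behavior in Short Sequence Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing predictive ("wager") versus reactive
    cursor behavior in short serial reaction time tasks. Provides
    first-order transition-entropy regularity scoring (G) for 4-symbol
    stimulus sequences, a constrained sequence generator, a synthetic
    cohort simulator producing 40 Hz cursor trajectories, click times,
    free-recall output and awareness ratings, trial-level trajectory
    measures (initial distance to next target, axis-maximum distance
    from the previous target) with threshold-based predictive/reactive
    classification, cross-recurrence recall matching, and a statistical
    stage with mixed-effects learning-curve models, uniformity
    chi-square tests of block proportion histograms, excess-score
    t-tests, recall regressions and residual-based mediation analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    sandwich,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
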