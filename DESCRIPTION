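Package: olfquest
Title: Olfactory Threshold Estimation with QUEST and Staircase Procedures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of olfactory detection thresholds on the discrete
    16-pen Sniffin' Sticks dilution scale using two adaptive procedures: a
    Bayesian adaptive (QUEST-style) engine with a grid posterior over
    threshold and a one-up/two-down transformed staircase. Includes a
    Weibull psychometric model for 3-alternative forced-choice responses,
    simulated observers and a synthetic test-retest cohort generator,
    threshold data-cleaning rules for runs that hit the ends of the pen
    range, and a reliability and method-agreement analysis suite
    (repeatability coefficient, Bland-Altman limits of agreement with
    exact-paired confidence intervals, and variance-corrected limits for
    between-method comparisons based on session means).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
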