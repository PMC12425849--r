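Package: nondirtest
Title: Non-Directional Tests for Within-Participant Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects within-participant effects whose sign varies across
    individuals and which therefore cancel out in standard group-level
    directional tests of trial-level behavioural data. Implements two
    non-parametric permutation tests (split-half sign consistency and
    absolute standardised effect size) built on a shared within-participant
    label-permutation engine, together with two established comparison
    tests (the prevalence global-null binomial test and the fixed-effects
    omnibus trial-level ANOVA), a library of signed per-participant summary
    statistics (mean difference, Cohen's d, d-prime, phi, response-
    conditional type-2 AUROC, interaction contrasts), participant exclusion
    rules, and a generative simulator for power and type-I-error
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
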