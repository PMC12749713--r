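Package: chronopls
Title: Latent Chronotype Subtypes from Multimodal Brain Imaging via
    Partial Least Squares
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised pattern learning for discovering latent subtypes of
    a binary chronotype trait (morningness vs eveningness) from multimodal
    imaging-derived phenotypes: grey-matter volumes, white-matter tract
    fractional anisotropy, and functional-connectivity link strengths.
    Fits a PLS1 latent-variable model of the -1/+1 encoded trait on
    concatenated brain feature blocks, assesses component significance by a
    target-shuffling permutation null, quantifies loading robustness by
    bootstrap resampling with Hungarian component matching and 5-95 percent
    percentile intervals, profiles components against behavioural,
    diagnostic and medication phenome families under per-family Bonferroni
    control, projects external cohorts measured on a feature subset into the
    trained latent space, and stratifies subtype expression by age bracket.
    A synthetic cohort generator with planted low-rank brain-target
    covariance modes, correlated background structure and a phenome with
    known latent associations makes every stage testable without access to
    restricted population data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
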