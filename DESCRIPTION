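Package: cusumlc
Title: Bernoulli CUSUM Learning Curves for Procedural Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential monitoring of procedural competence with Bernoulli
    cumulative sum (CUSUM) control charts derived from sequential probability
    ratio test boundaries. Computes scoring constants and decision intervals
    from acceptable and unacceptable failure rates, classifies operators as
    proficient, nonproficient or inconclusive with a two-boundary excursion
    rule, segments a pooled institutional chart into chronological proficiency
    intervals, and contrasts learning-environment covariates between intervals
    with multivariable logistic regression (maximum likelihood or Firth
    penalized likelihood). Includes a synthetic cohort generator with known
    ground truth and a Monte-Carlo estimator of the decision rule's operating
    characteristics, plus a reproducible end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
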