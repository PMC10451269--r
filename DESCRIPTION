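Package: engagekit
Title: Engagement Measurement for Robot-Assisted Autism Therapy Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the engagement of autistic children in
    robot-assisted therapy sessions from face-visible video. Implements a
    per-frame facial engagement classifier built on the valence-arousal
    circumplex model of affect (a frame is engaged when it falls in the
    positive-valence, high-arousal quadrant), a small convolutional network
    over rasterized 68-point facial landmarks, session-level engagement
    percentages from the model (engaged frames over total frames) and from
    therapist behaviour-assessment sheets (points over maximum points), and
    chance-corrected model-versus-therapist agreement via Cohen's kappa with
    the standard interpretation bands. A fully labelled synthetic session
    generator (schematic faces with ground-truth landmarks, Markov
    engagement dynamics, correlated therapist sheets) makes every stage
    testable end to end without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    EBImage,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    jpeg,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
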