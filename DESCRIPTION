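Package: salgaze
Title: Saliency and Semantic Feature Analysis of Gaze-Contingent Video Content
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing what observers look at in surveillance-style
    video. Extracts gaze-centered image patches from video clips, scores them
    with a six-channel spatiotemporal saliency model (luminance, two
    cone-opponent color channels, orientation, texture and optical-flow
    magnitude, with pyramid center-surround activation and a decaying temporal
    buffer), embeds them with a pluggable semantic feature backend, decodes
    observer group membership with elastic-net-regularised logistic regression
    over cumulative temporal windows, computes inter-subject correlations of
    attended features within and between groups, and scores violence-likelihood
    ratings with signal detection theory. Includes a synthetic stimulus and
    two-group gaze generator so the full pipeline is testable without any
    eye-tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
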