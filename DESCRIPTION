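Package: crowdmark
Title: Consensus Analysis of Crowdsourced Skin Demarcations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses crowdsourced demarcation studies of
    affected skin in patient photographs, as used for chronic
    graft-versus-host disease (cGVHD) surface-area assessment. Provides a
    synthetic study generator (multi-view images, heterogeneous-skill
    raters submitting node-bounded polygon demarcations), plurality-vote
    consensus masks, Dice and surface-area-error agreement metrics,
    per-rater reliability tracking with top-k crowd selection, learning
    curves, Mann-Whitney crowd comparisons, per-photo multi-angle error
    spread, and rater-variability versus consensus-error regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
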