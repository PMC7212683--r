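Package: aumix
Title: Facial Action-Unit Evidence Features and Model-Based Subgrouping of
    Affective Responsiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse spontaneous positive facial expression from
    frame-level facial action-unit (AU) evidence time series. Extracts
    per-participant average-evidence and area-under-the-curve features for
    the lip-corner puller (AU12) and cheek raiser (AU6), discovers
    responsiveness subgroups with finite Gaussian mixture models under the
    fourteen eigendecomposed covariance parameterisations selected by BIC,
    and performs rank-based covariate-adjusted group contrasts and partial
    Spearman correlations with caregiver-reported behavioural scales. A
    calibrated synthetic-cohort generator emulates the data structure of a
    funny-videos task (three clips of 13-20 s at 24 frames/s) so the whole
    pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
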