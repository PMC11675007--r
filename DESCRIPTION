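Package: csdconn
Title: Interhemispheric Functional Connectivity Dynamics Around Cortical
    Spreading Depolarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel local field potential (LFP)
    recordings around a unilateral cortical spreading depolarization (CSD)
    event. Provides moving-average detrending and ADC-saturation repair,
    nearest-neighbor (Kraskov-Stogbauer-Grassberger) estimators of mutual
    information and transfer entropy, connectivity evaluation in
    nonoverlapping 20-s windows over baseline and post-event segments, and
    the min-max group statistics with Bonferroni and consecutive-interval
    corrections used to test CSD-induced coupling changes. Includes a
    synthetic-data generator emulating CSD phenomenology (DC shift,
    ipsilateral AC hyperactivity, transient interhemispheric decoupling and
    unidirectional drive) plus analytic validation fixtures with closed-form
    information measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
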