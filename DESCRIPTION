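Package: mrcscan
Title: Multinomial Spatial Scan Statistics with Optimal Maximum Reported
    Cluster Size Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects spatial clusters in multinomial (nominal categorical)
    data with the spatial scan statistic over circular and elliptical
    scanning windows, with Monte Carlo inference that conditions on both
    the per-region and per-category totals. Implements the spatial cluster
    information criterion (SCIC, two versions) together with elbow, MCS-P
    and MCHS-P criteria for choosing the optimal maximum reported cluster
    size (MRCS), and a simulation framework with planted true clusters for
    scoring detection accuracy (sensitivity, positive predictive value,
    misclassification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
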