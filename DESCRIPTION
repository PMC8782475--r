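Package: npwma
Title: Distribution-Free Weighted Moving-Average Control Charts Based on
    the Wilcoxon Rank-Sum Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design and evaluation of distribution-free memory-type control
    charts for prospective monitoring of a process location parameter. The
    homogeneously weighted moving average (HWMA), double HWMA (DHWMA) and
    hybrid HWMA (HHWMA) schemes are built on the two-sample Wilcoxon
    rank-sum statistic computed between a fixed phase-I reference sample
    and a stream of phase-II test subgroups, so that the in-control run
    length does not depend on the (continuous) process distribution. The
    package provides the charting statistics with their time-varying
    control limits, the classical EWMA, double EWMA and CUSUM rank-sum
    competitors, a fast zero-state Monte Carlo run-length engine (average
    run length, its standard deviation, percentiles and expected values
    over shift grids), bisection calibration of control-limit constants to
    a nominal in-control average run length, synthetic process generators
    for normal, heavy-tailed and skewed families, and monitoring-report
    input/output including a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
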