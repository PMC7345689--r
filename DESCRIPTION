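Package: ccair
Title: Time-Stratified Case-Crossover Analysis of Air Pollution and
    Emergency Department Visits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating short-term associations between ambient
    air pollution and daily counts of emergency department visits using the
    time-stratified case-crossover design fitted by conditional
    quasi-Poisson regression with stratum effects eliminated.  Includes
    construction of daily exposure metrics from hourly multi-monitor data
    (daily means, daily maximum 8-hour ozone, the Canadian Air Quality
    Health Index), natural-spline temperature adjustment, relative risks
    scaled per interquartile range, a full subgroup-by-pollutant-by-lag
    analysis grid with significance mapping and period-split sensitivity
    analyses, and a calibrated synthetic-data generator for validation
    when confidential registry data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    splines,
    withr
Config/testthat/edition: 3
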