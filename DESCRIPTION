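Package: xmrorder
Title: Ordering Ambiguity in XmR Control Charts and Order-Free Outlier
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the control limits of an individuals and
    moving range (XmR) chart depend on the ordering of the data.
    Computes the average moving range, its exact minimum and maximum over
    all orderings of a data set via closed forms (verified against an
    exhaustive permutation oracle), permutation-resampled distributions
    of the statistic, and the order-free alternatives appropriate for
    data without an inherent ordering: Tukey's fences and the
    average-and-standard-deviation (3-sigma) chart.  Includes minimal
    p-, np-, c- and u-chart limits to demonstrate their permutation
    invariance, a synthetic generator for right-skewed bounded
    percentage data, and an ambiguity report summarising the
    order-dependence of a data set with a chart recommendation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
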