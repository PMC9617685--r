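Package: ascept
Title: Automated Selection of Changepoints Using Empirical P-Values and Trimming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects mean-shift changepoints in a univariate, regularly spaced
    time series in two stages: (1) exact penalized segmentation (PELT) swept
    over a penalty range (CROPS) to build a candidate path of nested
    changepoint sets, walked with fixed-sequence Monte-Carlo significance
    tests of the Gaussian log-likelihood improvement; and (2) trimming of
    nuisance changepoints that lie inside linear or seasonal trends, judged
    by the ratio of cross-segment to piecewise regression fit (linear and
    harmonic) root mean square errors.  Also provides a segment correction
    procedure that detrends or deseasonalizes segments and maps them onto the
    location and scale of a reference segment, a synthetic fixture generator
    with known ground truth, CSV ingest, structured reports, and a
    command-line interface.  Designed for population-level mobile-health
    series such as daily medians of wearable-device variables, where vendor
    algorithm updates induce abrupt technological shifts that must be
    separated from behaviorally driven trends.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
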