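Package: snakemap
Title: Mapping Snakebite Surveillance Incidence and Detecting Likely Underreporting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for municipality-level analysis of snakebite surveillance
    data in settings where reporting is incomplete. Implements a six-variable
    rank-sum "underreporting index" with quantile categories, a within-region
    dual-rank "low-reporter" detector (large rural population combined with low
    reported incidence), Poisson regression of case counts with a log-population
    offset yielding incidence ratios with Wald confidence intervals, descriptive
    incidence and seasonality summaries (circular five-week sliding means), a
    reproducible environmental-region clustering of municipalities from
    altitude, precipitation and location, and a synthetic-country generator
    with deprivation-dependent reporting so that every stage can be validated
    against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
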