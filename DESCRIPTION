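Package: gmapredict
Title: Geographical Momentary Assessment Pipelines for Forecasting Craving and Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for geographical momentary assessment (GMA) studies that
    combine passive GPS logging with randomly prompted ecological momentary
    assessment (EMA) ratings. The package cleans raw GPS tracks with an
    iterative implausible-velocity filter, rasterizes property-tax values to a
    30 m exposure surface with inverse-distance road fill, links exposure to
    EMA ratings through 30-minute bins and 5-hour feature windows, trains
    person-tailored random-forest classifiers under a leave-one-out
    week-by-week tailoring protocol to forecast heroin craving, cocaine
    craving, or stress 90 minutes ahead, and decomposes prediction accuracy
    (sensitivity, specificity, PPV, NPV) by person, demographic group, and
    empirically clustered prevalence trajectory via latent-class growth
    models and random-intercept multilevel models. A synthetic-data module
    generates complete study datasets (exposure surface, GPS tracks, EMA
    records, participant profiles) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
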