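Package: climsent
Title: Spatiotemporal Poisson Relative-Risk Modelling of Climate and
    Social-Media Sentiment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking weekly climate covariates to negative-sentiment
    counts on a region network with a Poisson relative-risk model. The linear
    predictor combines a separable space-time Gaussian Markov random field
    (intrinsic CAR in space, first-order autoregression in time) with
    categorized covariate random effects, fitted by a constrained Gaussian
    (Laplace) approximation with empirical-Bayes hyperparameters. Includes a
    lexicon-based text pipeline that aggregates geotagged documents into
    weekly region panels, covariate categorization and event-window labelling,
    a synthetic-data generator with known ground truth for validation, and a
    one-call pipeline from raw documents to effect summaries and
    relative-risk difference maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
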