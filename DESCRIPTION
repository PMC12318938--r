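Package: wheatmoe
Title: County-Level Wheat Yield Estimation with a Sparse Mixture-of-Experts Sequence Model
Version: 0.1.0
Authors@R:
    person("wheatmoe", "maintainers", email = "wheatmoe@example.org", role = c("aut", "cre"))
Description: Estimates county-level wheat yield from monthly growing-season
    trajectories of vegetation indices (NDVI, EVI, NIRv, red reflectance),
    biophysical variables (LAI, Fpar), meteorology (relative humidity,
    radiation) and static terrain/soil covariates (DEM, SoC). The estimator is
    a hybrid sequence-regression network: a Transformer encoder branch and a
    bidirectional LSTM branch feed a dynamically gated pool of five
    heterogeneous expert networks with sparse Top-2 activation, followed by a
    fusion head. Training (Huber loss, Adam, gradient clipping), fixed-year and
    leave-one-year-out rolling evaluation, progressive in-season truncation,
    Shapley-style feature attribution, correlation screening, an analytic FLOP
    counter, ablation variants, and a synthetic multi-source data generator are
    included, together with a file-based CLI. The network and its
    backpropagation are implemented in base R.
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
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
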