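Package: corridorsdm
Title: Ensemble Species Distribution Models and Least-Cost Corridor Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for predicting dispersal corridors from occurrence data and
    categorical land-cover rasters. Fits an accuracy-weighted ensemble of
    species distribution models (ridge-stabilised logistic GLM, gradient
    boosting, and a maximum-entropy model) on fractional-cover covariates,
    projects and integrates per-area suitability maps, converts suitability to
    a resistance surface by exponential decay, and computes synoptic
    connectivity with factorial least-cost paths and cumulative resistant
    Gaussian kernels. Includes a virtual-species landscape simulator so the
    whole pipeline is testable without external spatial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
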