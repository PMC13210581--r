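Package: ensdm
Title: Ensemble Species Distribution Modelling with TSS-Weighted
    Ensembles and Habitat-Change Analysis
Version: 0.1.0
Authors@R:
    person("Miao", "Developer", email = "dev@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for ensemble species distribution
    modelling on regular longitude/latitude grids: occurrence-record
    cleaning and spatial thinning, collinearity screening of bioclimatic
    predictors (pairwise correlation and stepwise variance-inflation
    elimination), pseudo-absence sampling with equal-prevalence
    weighting, replicated calibration/evaluation splits over pluggable
    probabilistic base learners, TSS-gated proportional-weight ensemble
    prediction on a 0-1000 suitability scale, cutoff-anchored Jenks
    habitat classification with equal-area statistics and change rates,
    and area-weighted centroid-shift analysis with geodesic distances
    and compass sectors.  Includes a synthetic-data generator (Gaussian
    random-field predictor stacks, a known true suitability model, and
    contaminated occurrence tables) so the whole pipeline is testable
    against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
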