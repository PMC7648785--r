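Package: mixmediate
Title: Multivariate Mediation Analysis for Environmental Exposure Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analytical framework for mediation analysis of correlated
    environmental exposure mixtures and high-dimensional biomarker mediators
    in nested case-control studies. Implements inverse-probability-weighted
    pairwise counterfactual mediation with product-of-coefficients effect
    decomposition, environmental risk scores via adaptive elastic net,
    Bayesian shrinkage mediation with posterior inclusion probabilities,
    directions of mediation and mediator group effects, pathway-product
    penalization (pathway lasso), minimax concave penalty with joint
    significance testing, and sensitivity analyses (error-correlation
    curves, E-values, covariate-subset scans). Includes a synthetic cohort
    generator with known ground-truth effects for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
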