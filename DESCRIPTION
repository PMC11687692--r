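Package: floeseal
Title: Segmented Negative Binomial Models of Pack-Ice Seal Occupancy on Sea-Ice Floes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the number of pack-ice seals hauled out on
    individual sea-ice floes as a function of floe area and fine-scale
    environmental covariates. The statistical core is a segmented (broken-stick)
    negative binomial GLM whose breakpoints in floe area are estimated by
    iterative linearization of the hinge basis, with per-segment slopes,
    delta-method breakpoint standard errors and AIC-based candidate-distribution
    comparison. Around it sit a synthetic scene generator (ice-floe fields,
    spectrally synthesized bathymetry, penguin colonies, negative binomial seal
    counts), per-floe covariate extraction from raster masks (sea-ice
    concentration in metric buffers, focal bathymetric slope/TRI/roughness,
    colony distance, edge-buffer filtering, stratified size-bin sampling),
    variable importance via conditional permutation on a regression forest,
    all-subsets AIC model ranking, cross-validation, and bootstrap confidence
    and prediction intervals for floe- and scene-level abundance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    randomForest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
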