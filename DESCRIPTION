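Package: cuphytox
Title: Copper Dose-Toxicity Modelling for Plant Bioassays Across Soils
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing copper phytotoxicity bioassays conducted
    across soils with contrasting properties. Fits per-soil log-logistic
    dose-response curves on EDTA-extractable Cu, derives EC10/EC50
    thresholds with bootstrap confidence intervals and leaching factors,
    regresses log-thresholds on soil properties with forward predictor
    selection, and fits a joint dose-response model in which the curve
    location and slope are linear functions of soil covariates (pH,
    organic carbon, cation exchange capacity, Mn oxides). Includes a
    synthetic bioassay generator reproducing a pH-stratified spiking
    design over 17 reference Chinese agricultural soils, so the whole
    pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
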