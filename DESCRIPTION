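Package: vespabund
Title: Species Abundance and Risk Modelling for the Yellow-Legged Hornet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the local abundance of the invasive hornet
    Vespa velutina nigrithorax from environmental covariates, and for mapping
    the downstream risk it poses to people and apiculture. The package
    simulates synthetic landscapes (bioclimatic fields, categorical land
    cover, trap-survey counts, administrative units), builds covariates from
    land-cover composition within a foraging-radius buffer, fits tree-ensemble
    species abundance models (random forest and gradient boosting, raw and
    log1p responses) alongside occurrence-based species distribution models,
    evaluates them with replicated stratified splits (standardized mean
    absolute error, Pearson correlation, calibration slope, AUC), selects
    variants by rank sums, and converts predicted abundance into
    hazard-times-sensitivity risk indices aggregated over administrative
    units.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    xgboost,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
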