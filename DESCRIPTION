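Package: ectoclim
Title: Mechanistic Climate-Vulnerability Modelling for Small Ectotherms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for assessing climate vulnerability of
    small diurnal ectotherms such as grass lizards. Converts monthly climate
    normals into hourly microclimates, runs a lumped heat- and water-budget
    simulation of behavioural thermoregulation (operative temperature,
    activity time, metabolic rate, evaporative water loss, thermal safety
    margin), fits degree-day embryonic development models, builds hybrid
    species-distribution ensembles that combine bioclimatic and biophysical
    predictors with TSS-weighted averaging, and attributes projected
    suitability change to individual predictors via response curves. Includes
    a parametric synthetic-world generator (climate grids, virtual species,
    occurrence sampling) so the whole pipeline is testable without external
    data downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    geosphere,
    glmnet,
    ranger,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
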