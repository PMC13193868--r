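Package: octrao
Title: Quantitative OCT Biomarkers for Acute Central Retinal Artery Occlusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for optical coherence tomography
    (OCT) biomarkers of acute central retinal artery occlusion (CRAO).
    Implements a mechanistic synthetic-cohort simulator of paired CRAO/fellow
    macular volumes, an open raster + sidecar OCT container, inner/outer
    retinal layer (IRL/ORL) reflectivity extraction with sub-pixel boundary
    weighting, ETDRS sector thickness maps and the relative retinal thickness
    increase (RRTI), non-parametric group tests with exact small-sample
    enumeration, empirical ROC/AUC with Youden cut-point optimization,
    time-to-OCT trend regression, chained-equation imputation and an
    exploratory logistic classifier for stratification at the 4.5-hour
    reperfusion window.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
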