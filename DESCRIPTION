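Package: riceNNI
Title: In-Season Rice Nitrogen Diagnosis and Precision Topdressing from
    Canopy Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing the in-season nitrogen status of rice and
    translating that diagnosis into stage-split fertilizer topdressing
    recommendations.  Implements construction of critical nitrogen dilution
    curves (Nc = a * DM^-b) by the Justes grouping procedure, the nitrogen
    nutrition index (NNI), nine multispectral vegetation indices with
    soil-background masking, gray relational analysis for index screening,
    random-forest inversion of NNI from selected indices, a linear-plateau
    model of the NNI to relative-yield response, and a nitrogen-balance
    calculator that converts a yield target into basal plus stage-wise
    topdressing amounts.  A synthetic trial generator with a known truth
    structure supports testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
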