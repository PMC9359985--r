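Package: sdmtransfer
Title: Ensemble Species Distribution Models and Spatial Transferability Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-background species distribution modeling with an
    ensemble of base algorithms (weighted logistic regression, surface
    range envelope, classification trees, gradient boosting), performance
    weighted ensemble and committee averaging, threshold optimization by
    maximum sensitivity plus specificity, permutation variable importance,
    and a spatial transferability assessment comparing region
    cross-validation against background-restricted extrapolation using
    Spearman map correlation and the Schoener's D and Hellinger's I niche
    overlap indices. Includes a virtual-species landscape generator with
    known ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
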