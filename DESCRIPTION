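Package: socgwr
Title: Soil Organic Carbon Stock Mapping with Geographically Weighted
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for mapping soil organic carbon (SOC)
    stocks from layered soil-profile observations and gridded environmental
    predictors. Computes fixed-depth (0-100 cm) SOC stocks, removes
    per-ecoregion interquartile-range outliers, normalizes the skewed stock
    distribution with a profile-likelihood Box-Cox transform, screens
    candidate predictors by Pearson correlation pruning and best-subset
    multiple regression under F-test significance, and fits a geographically
    weighted regression (GWR) with adaptive nearest-neighbour bandwidth
    selected by corrected-AIC minimization. Fitted local coefficient fields
    drive space-for-time climate-scenario projections of decadal SOC change,
    zonal aggregation to ecoregions, residual bias diagnostics, and a
    principal component analysis relating local coefficients to regions.
    Includes a synthetic-landscape generator with known spatially varying
    coefficient surfaces so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
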