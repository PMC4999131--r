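Package: agroclim
Title: Growth-Stage Agro-Climatic Indicators, Conditional Inference
    Forest Variable Importance and Weather-Pattern Clustering for Crop
    Yield Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for data-driven agronomy linking daily weather series
    to rice yields. Prepares station weather records (WMO-style quality
    control, hourly-to-daily aggregation, Angstrom-Prescott solar
    radiation from sunshine duration, station merging, vector-
    autoregressive and random-forest gap filling), builds cropping
    events with cultivar-proportional growth-stage splits and the
    standard set of 27 stage indicators, fits conditional inference
    regression forests with conditional permutation variable importance
    aggregated over run ensembles with Kruskal-Wallis letter grouping
    and partial dependence profiles, and classifies cropping events by
    their full daily weather patterns using dynamic time warping
    distances and Ward hierarchical clustering. A synthetic weather and
    yield generator with known ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    randomForest,
    geosphere,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
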