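Package: nestage
Title: Inferring Breeder Age Classes from Egg Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer the age class of breeding seabirds from easily
    measurable nest variables. Implements egg-volume feature construction
    (volume = 0.000476 * length * width^2), Gaussian GLM selection over
    competing age parameterizations ranked by AIC, and a balanced-subsample
    bootstrap ensemble of random-forest classifiers with out-of-bag
    accuracy, sensitivity and specificity, aggregated Gini importances,
    misclassification-consistency reports, learning curves and chi-square
    comparison of young-breeder proportions. Ships a seeded synthetic
    colony generator so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
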