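Package: benthicGP
Title: Linking Benthic Macroinvertebrate Diversity Indices to Water
    Physicochemistry by Genetic Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for freshwater bioassessment studies that relate benthic
    macroinvertebrate community structure to routinely measured water-quality
    variables. Computes Shannon, Simpson and Margalef diversity indices from
    station-by-month count tables; screens physicochemical predictors by
    Pearson correlation, collinearity pruning, K-means seasonal stratification
    (with winter-cluster exclusion) and varimax-rotated principal components;
    and searches for closed-form index equations by multi-restart tree-based
    genetic-programming symbolic regression, reporting variable-presence
    tallies across restarts and train/validation goodness-of-fit summaries.
    A synthetic-data generator with a planted environment-to-diversity link
    supports end-to-end recovery testing when field data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
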