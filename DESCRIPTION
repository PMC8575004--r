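Package: sfstrat
Title: Similarity-Stratified Benchmarking of Binding-Affinity Scoring Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how training/test set similarity shapes the scoring
    power of protein-ligand binding-affinity scoring functions. Builds nested
    training sets from protein-structure, ligand-fingerprint and pocket-topology
    similarity matrices under similarity cutoff schedules, re-calibrates classical
    multiple-linear-regression scoring functions (X-Score, Vina, Cyscore feature
    sets) and their random-forest and gradient-boosting counterparts on each
    nested set, and evaluates Pearson/Spearman correlation and RMSE versus
    cutoff, including crossing-point and sharp-leap detection. Ships a
    self-contained synthetic benchmark generator with planted ground truth so
    the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
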