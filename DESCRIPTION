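Package: metconn
Title: Metabolic Brain Connectivity Networks from FDG-PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-level metabolic connectivity analysis for FDG-PET cohorts.
    Builds cross-subject interregional Pearson correlation networks from
    registered PET volumes or precomputed subject-by-region uptake tables,
    tests edgewise group differences with max-statistic permutation
    familywise-error control, and characterises network topology over a
    proportional density sweep (clustering coefficient, global efficiency,
    characteristic path length, and small-worldness against degree-preserving
    rewired null networks). Includes a synthetic-cohort generator with
    modular covariance and planted group effects for validation, and
    exporters for BrainNet-style node and edge files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
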