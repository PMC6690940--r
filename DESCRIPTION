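Package: islandpe
Title: Insular Phylogenetic Endemism and Categorical Endemism Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes expanded and restricted insular phylogenetic endemism
    (PE) on a dated genus-level phylogeny and an island-by-genus
    presence/absence matrix, together with the uniform-branch-length
    alternative (PEalt) and their ratio (relative phylogenetic endemism,
    RPE). Observed values are tested against a fixed row- and column-sum
    randomization null model and islands are classified into paleo-, neo-,
    mixed- and super-endemism categories. Includes occurrence-record
    cleaning (native-status and native-range bounding-box filters),
    under-sampling exclusion via a species-area richness model, an
    incidence-based coverage estimator (ICE) for sampling completeness,
    a synthetic-data generator with plantable endemism signals, and a
    coverage-threshold sensitivity sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    utils,
    vegan
Suggests:
    phangorn,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
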