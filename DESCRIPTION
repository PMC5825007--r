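Package: reserveplanr
Title: Reserve Selection and Gap Analysis for National Plant Biodiversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable pipeline for national-scale plant biodiversity
    conservation assessment: simulate landscapes, virtual species and
    survey-style occurrence data; fit multi-response multivariate adaptive
    regression spline (MARS) species distribution models with inventory
    pseudo-absences; binarize occurrence probabilities with data-driven
    thresholds; select complementary reserve networks with a Marxan-style
    simulated-annealing optimizer (boundary-length penalties, repeat runs,
    summed-solution irreplaceability scores, area-capped networks); and
    report representation by species group, range size and elevation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
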