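Package: coastweb
Title: Robustness and Bioenergetic Dynamics of Coastal Food Webs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the robustness of coastal marine food webs to
    species loss and for simulating their biomass dynamics under fishing and
    plankton-productivity change. Implements static extinction cascades under
    ordered deletion sequences with the R50 robustness index, short-weighted
    trophic levels and structural null models, and an Allometric Trophic
    Network (ATN) bioenergetic model extended with a constant plankton subsidy
    and per-species fisheries mortality, run through factorial
    fishing-by-subsidy perturbation designs. Includes a niche-model based
    synthetic food-web generator emulating an intertidal web with a plankton
    node, specialist filter-feeders and a fisheries node.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
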