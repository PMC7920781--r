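Package: pollinet
Title: Quantitative Plant-Pollinator Network Modularity, Topological Roles,
    and Sampling Completeness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for weighted bipartite plant-pollinator visitation
    networks. Builds weighted interaction matrices from tidy visitation
    records (with full, reduced, location, consecutive-year and seasonal
    subsetting), computes Barber's quantitative bipartite modularity with a
    seeded multi-restart label-propagation optimizer and an exhaustive
    small-network oracle, standardizes observed modularity against
    quantitative 'vaznull' null ensembles (Z_Q), assigns strength-based
    weighted c/z topological roles (peripheral, connector, module hub,
    network hub) against null-derived critical thresholds, estimates
    sampling completeness via Chao1 richness and interaction rarefaction,
    summarises per-plant visitation, and generates synthetic visitation
    data with planted module structure so the whole pipeline can be
    exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
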