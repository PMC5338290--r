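Package: phytophagnet
Title: Chemically Annotated Plant-Herbivore Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds bipartite insect-plant interaction networks, scores
    family-level feeding specificity against degree-preserving null models,
    and contrasts taxonomy-driven ("feed-on-family") against
    chemistry-driven ("feed-on-compound") host selection. Implements the
    plant family-based evenness index, the food-pairing statistic (mean
    number of compounds shared among a herbivore's host plants), a
    per-plant coefficient of compound contribution, and a Fisher's exact
    test / Cramer's V screen for compounds specific to the host plants of
    a herbivore clade. A synthetic-data generator with planted ground
    truth makes every statistic testable and calibratable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vegan,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
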