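Package: adrank
Title: Topological-Index Based Multi-Criteria Ranking of Drug Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes degree-based topological indices (first and second
    Zagreb, hyper-Zagreb, harmonic, forgotten, sum-connectivity) from
    hydrogen-suppressed molecular graphs, derives objective criterion
    weights by the entropy method, ranks drug candidates with TOPSIS and
    simple additive weighting (SAW), and relates indices to
    physicochemical properties through simple-regression QSPR to assign
    benefit/cost criterion directions. Includes seeded generators for
    random bounded-degree molecular graphs, positive decision matrices,
    and property tables with planted linear structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
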