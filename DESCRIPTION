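Package: sprawlrisk
Title: Multi-Scenario Urban-Growth Simulation and Ecological Risk Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-class urban land-use change with a revised-Markov
    demand model, random-forest transition-rule mining and a patch-seeding
    cellular automaton that couples organic (edge-adjacent) and spontaneous
    (detached-patch) growth, then maps the ecological risk of construction-land
    expansion from ecosystem-service and sensitivity indicators aggregated over
    a fishnet of risk zones. Includes a seeded synthetic-region generator so the
    full pipeline is testable without external GIS data, agreement metrics
    (overall accuracy, Kappa, figure of merit), least-cost minimal-cumulative-
    resistance surfaces and Jenks natural-breaks grading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
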