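Package: carestress
Title: Stress-Testing the Resilience of Outpatient Care Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient-sharing networks between physicians from
    administrative visit records, estimates physician capacities from
    opening hours and quarterly patient contacts, and stress-tests
    regional healthcare provision with an agent-based patient-displacement
    model. Physicians are removed from the network either one at a time
    (slow-onset shocks such as retirement waves) or in a single large
    shock (e.g. mass quarantine), displaced patients relocate along the
    empirical patient-sharing network subject to capacity and travel
    distance constraints, and the package derives regional resilience
    indicators: lost-patient and free-capacity curves, critical limits,
    and per-physician risk and benefit scores. A synthetic-data generator
    emulates the statistical structure of claims data so the full pipeline
    runs without access to restricted records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    igraph,
    geosphere,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
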