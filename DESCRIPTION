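Package: treecarbon
Title: Supply and Demand Accounting for Urban Tree Carbon Storage and
    Sequestration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies and maps the supply of and demand for carbon
    storage and sequestration by urban trees at the census-tract level.
    Computes per-tree aboveground biomass and whole-tree carbon from
    allometric equations, simulates one year of forest dynamics
    (size-dependent mortality, species-group growth, decomposition under
    removal, mulching and natural-decay regimes, and replanting) to
    estimate net annual carbon sequestration, derives a demand proxy
    from sectoral anthropogenic CO2 emissions, and maps a tract-level
    supply-to-demand ratio classified with Jenks natural breaks. Ships a
    seeded synthetic-inventory generator so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
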