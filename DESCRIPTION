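Package: kelpDOC
Title: Senescence-Driven Dissolved Organic Carbon Production by Giant Kelp
Version: 0.1.0
Authors@R:
    person("Kelp", "Carbon Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for partitioning giant kelp (Macrocystis pyrifera) net primary
    production into dissolved organic carbon (DOC) release. Computes NPP, DOC
    exudation and percent extracellular release from closed-chamber blade
    incubations; classifies blades by light regime and physiological maturity;
    analyses exudate sugar composition (mole percentages, PCA, PERMANOVA,
    Model II regression); tracks the age structure of satellite-derived kelp
    canopy biomass with a daily cohort ledger and modified-Akima interpolation;
    and upscales bootstrap rate distributions to regional annual DOC production
    with and without senescence. Includes seeded synthetic-data generators for
    both incubation tables and pixel biomass time series so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
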