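Package: ionoflux
Title: Stoichiometric Interrogation of Carotenoid- and Ionone-Producing Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based (flux balance) analysis of Saccharomyces
    cerevisiae strains engineered for beta-carotene accumulation and its
    oxidative cleavage to beta-ionone. Reads and writes genome-scale
    metabolic models (COBRA-style JSON and SBML Level 3 with FBC
    annotations), grafts the heterologous carotenogenic and apocarotenogenic
    reactions (CrtE, CrtYB, CrtI, CCD1 single and double cleavage) onto a
    host model with verified elemental balance, converts shake-flask strain
    measurements (growth rate, CO2 evolution, carotenoid yields, ionone
    titers) into flux constraints, and runs four model-interrogation
    procedures: minimal glucose uptake prediction with relative error,
    carbon-recovery accounting, counterfactual maximum beta-ionone yield
    with cleavage departure, and the C14-dialdehyde to ionone molar ratio.
    Includes a synthetic-data module that builds toy host networks with
    closed-form optima and simulates strain measurements for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
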