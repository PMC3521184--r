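Package: photoflux
Title: Constraint-Based Comparison of C3 and C4 Photosynthetic Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative constraint-based analysis of C3 and
    C4 plant metabolism. Computes the Rubisco carboxylation:oxygenation
    ratio from Farquhar-type leaf kinetics for C3 leaves and from the
    two-cell von Caemmerer model for C4 leaves, installs the resulting
    combined Rubisco reaction into stoichiometric models, and runs flux
    balance analysis, single-deletion knockout scans, artificial-centered
    hit-and-run flux sampling with correlated reaction set detection,
    reaction-graph topology metrics, environment (light, CO2) sweeps and
    C4 decarboxylation-subtype scenarios. Ships deterministic toy C3 and
    C4 models (Calvin cycle, photorespiratory C2 cycle, light reactions,
    TCA, mesophyll/bundle-sheath shuttle) so every stage is testable
    without genome-scale reconstructions; user-supplied models are read
    from a TSV dialect or an SBML subset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
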