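Package: gutferm
Title: Fermentation Balances and Community Responses in Anoxic Gut-Content Microcosms
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing anaerobic fermentation experiments in sealed
    gut-content microcosms. Converts raw headspace and liquid-phase
    measurements into total analyte amounts per gram fresh weight (ideal-gas
    headspace amounts, Bunsen-coefficient gas solubility, carbonate
    speciation via the first dissociation constant), computes net
    fermentation-product profiles over unsupplemented controls, and closes
    carbon and reducing-equivalent (electron) balances from biomass
    elemental chemistry (degree of reduction per carbon under a fixed
    oxidation-state convention). Also implements an amplicon responder
    screen on taxa-by-sample count tables (family and phylotype
    increase-over-control thresholds, similarity-based phylotype merging,
    time-averaged abundances, Shannon and expected-richness summaries) and
    a synthetic-data module that generates measurement tables and count
    tables with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
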