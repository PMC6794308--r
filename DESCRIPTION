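Package: odzn2
Title: Productivity, Placement-Based Quantification and Nitrogen-Loss
    Budgets for Oceanic Oxygen-Deficient Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools linking mixed-layer productivity estimates from triple
    oxygen isotopes and O2/Ar dissolved-gas measurements, sediment-trap
    organic-matter flux budgeting, phylogenetic-placement read
    quantification of marker genes in metagenomes, and an electron-balance
    denitrification-anammox stoichiometry that converts organic-carbon flux
    consumed in an oxygen-deficient zone into N2 production rates and
    accumulated biogenic N2. Includes air-sea gas-exchange
    parameterizations (Schmidt number, oxygen solubility, wind-history
    weighted piston velocity), Monte Carlo uncertainty propagation, 13C
    incubation rate calculations, jplace ingestion, copy-number corrected
    abundance tables, virus-to-host marker ratios, peptide-overlap
    statistics, and a synthetic-data generator with known ground truth for
    every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
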