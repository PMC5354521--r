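Package: cellergy
Title: Bioenergetic Cost Accounting for Cells and Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: ATP-denominated cost accounting for single cells: biosynthetic
    costs of glycerophospholipids from chain length and unsaturation, cell
    maintenance and growth energy budgets scaling with volume, membrane lipid
    costs and their apportionment across compartments, packing densities and
    required turnover rates of ATP synthase and electron-transport-chain
    complexes, allometric power-law fitting on log-log scales with
    standard-error algebra on exponents, and a synthetic cross-species trait
    generator with multiplicative lognormal scatter for testing fitting and
    budget pipelines. Relative costs are interpretable as selection
    coefficients and can be compared against the drift threshold set by
    effective population size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
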