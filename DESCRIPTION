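Package: efloatr
Title: Algal Bloom Harvesting Analysis: Flocculation, Microflotation,
    Resource Recovery and Techno-Economic Scale-Up
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing microflotation-based harvesting of
    algal blooms from eutrophic water bodies. Computes flocculant
    dose-response curves and operating-dose selection, first-order
    flotation kinetics, recoverable lipid, phosphate and protein mass
    balances, fatty acid methyl ester (FAME) saturation profiles,
    microbial community diversity summaries (relative abundance
    aggregation and Shannon index), and a modular full-scale
    techno-economic model (air demand, compressor derating, batch
    scheduling, energy and flocculant operating costs, capital costs,
    solar sizing). Includes seeded synthetic-data generators emulating
    each input type so the whole pipeline is testable without field
    data, and a bundled water-retention-pond case study.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
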