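Package: quadfold
Title: Topology Enumeration and Melting Thermodynamics of Intramolecular
    G-Quadruplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the folding landscape of intramolecular
    G-quadruplexes built on a snapback-loop, G-vacancy architecture.
    Parses G-rich sequences with extended residue codes (inosine, abasic
    sites, 8-bromo-dG), decomposes them into G-tracts and loops,
    enumerates feasible folding topologies under loop-length and
    helicity constraints with Webba da Silva descriptors, derives
    glycosidic (syn/anti) variants and tetrad stacking polarities, and
    scores competing folds with a configurable additive free-energy
    model converted to Boltzmann populations. Implements the full
    two-state UV-melting workflow (baseline extrapolation, folded
    fraction, melting temperature, van't Hoff regression, Gibbs free
    energies and replicate statistics) together with a synthetic
    melting-curve generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
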