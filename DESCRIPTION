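Package: provtraits
Title: Trait Derivation and Variance Partitioning for Tree Provenance Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing common-garden provenance trials of forest
    trees, with an emphasis on branch xylem hydraulics. Derives vessel-level
    wood-anatomical traits and theoretical (Hagen-Poiseuille) hydraulic
    conductivities from cross-section measurements, fits sigmoid xylem
    vulnerability curves to percent-loss-of-conductivity data and extracts
    P12/P50/P88 cavitation thresholds, computes allometric stem volume and
    aboveground biomass, and summarises climate-of-origin aridity (forest
    aridity index, Ellenberg quotient). A restricted-maximum-likelihood
    engine partitions trait variance into inter-provenance, block and
    residual components with boundary-corrected likelihood-ratio tests, and
    a seeded simulator generates complete virtual trials for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
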