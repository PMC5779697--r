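Package: lipidlens
Title: Differential Analysis of Shotgun Lipidomics Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end differential analysis of quantitative shotgun
    lipidomics data: parsing of shorthand lipid species nomenclature,
    mole-percent normalization with abundance-aware missingness handling,
    class-level Mann-Whitney comparisons, per-species 2x2 factorial linear
    models with genotype, intervention and interaction tests under
    Benjamini-Hochberg control, regulation-group clustering of test
    statistics, dual-threshold fold-change classification, acyl-chain
    matched PC/PE ratio testing, and a covariate-adjusted (age, body mass
    index) robust-regression arm for case/control cohorts. Includes a
    seeded synthetic lipidome simulator with planted effects and
    ground-truth recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
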