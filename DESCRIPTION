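Package: pmvlogp
Title: Partial-Molar-Volume-Corrected Solvation Free Energies and
    Octanol-Water log P from Integral-Equation Energy Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for solvation thermodynamics computed
    with embedded-cluster integral-equation theory (EC-RISM). Takes tables of
    per-state energy components (electronic energy in solution, uncorrected
    excess chemical potential, partial molar volume, gas-phase energy) for
    tautomer/conformer ensembles of small molecules, applies a linear
    correction to the excess chemical potential, aggregates states through
    discrete partition functions, and predicts solvation Gibbs energies and
    direct octanol-water partition coefficients (log P). Includes nonlinear
    training of the correction parameters against experimental solvation
    free energies, blind-challenge evaluation statistics, tautomer stability
    analysis, a synthetic-data generator with known ground truth, and a
    command-line interface.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
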