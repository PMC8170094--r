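Package: redoxleak
Title: Electron-Transfer Side Reactions and Superoxide Production at the
    Qo-Site of the Cytochrome bc1 Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation inference chain for quantifying a
    superoxide-producing electron-transfer side reaction at the Qo-site of
    the cytochrome bc1 complex. Classifies quantum-chemistry snapshots into
    electron-transfer outcomes from fragment spin densities, quantifies
    oxygen (un)binding kinetics from distance time series via survival
    analysis, constructs energy-gap linear-response free-energy diagrams
    (driving force and reorganization energies), estimates alchemical
    free-energy differences by exponential averaging and the Bennett
    acceptance ratio, and converts the free-energy parameters into Marcus
    and Moser-Dutton electron-transfer rates and a combined superoxide
    production rate. Includes seeded synthetic-data generators with known
    ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
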