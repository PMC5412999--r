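Package: ionex
Title: Strict Charge-Neutral Ion-Exchange Modeling of Ion Adsorption on
    Mineral Surfaces
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Coupled aqueous and surface equilibrium speciation for strict
    charge-neutral, multi-site ion-exchange models of ion retention on
    mineral surfaces such as goethite.  Forward-predicts pH-dependent
    adsorption envelopes for protons, sodium, chloride and phthalate from
    mass-action and mass-balance equations in which every surface species
    is electrically neutral, accounts for the conjugate ions introduced by
    acid/base pH adjustment, applies published measurement offsets, and
    estimates exchange constants (pK values) by single-datum solves or
    staged, tied least-squares optimization over envelope data.  Includes
    in-package scenario fixtures, a synthetic-envelope generator for
    parameter-recovery studies, ggplot2 visualisations, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
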