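Package: phaseplan
Title: Design and Analysis of Microbatch-Under-Oil Crystallization Phase Diagrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for mapping protein crystallization phase diagrams with
    automated microbatch-under-oil experiments. Designs diagonal-sampling
    plates from four user-defined corner conditions, computes per-well
    four-channel dispense volumes with feasibility and consumption
    accounting, classifies paired seeded/unseeded drop outcomes into
    phase-diagram zones (undersaturated, metastable, nucleation,
    precipitation), estimates monotone phase boundaries, designs seed-stock
    serial-dilution titration plates, and computes batch scale-up recipes.
    A built-in parametric phase-diagram simulator (log-quadratic solubility
    with supersaturation thresholds) makes the whole design-to-classification
    loop testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
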