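Package: polarDA
Title: Conceptual-DFT Reactivity Analysis for Polar Diels-Alder Reactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the reactivity and regioselectivity of
    Diels-Alder partners from ground-state electronic-structure summaries.
    Computes conceptual-DFT global indices (chemical potential, hardness,
    electrophilicity, nucleophilicity) and local indices from Parr
    functions, classifies reaction pairs by electrophilicity difference
    (polar versus non-polar), electron-density flux direction and predicted
    bond pair, performs topological analysis of the electron localization
    function (ELF) on cube-format scalar fields (attractors, basins,
    populations, synapticity, Lewis-like summaries), and fits Hammett
    linear free-energy models of reaction polarity against substituent
    constants. Ships a deterministic synthetic-data generator so every
    stage is testable without external quantum-chemistry output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
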