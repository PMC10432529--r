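Package: phyllocomp
Title: Metabolic Resource Overlap and Single-Cell Reproductive Success in
    Bacterial Competition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for pairwise bacterial competition in defined
    media and on leaf surfaces. Fits logistic growth curves from microplate
    readings and derives carbon-utilisation profiles; computes flux-balance
    growth, minimal nutritional requirements and the metabolic resource
    overlap (MRO) index for constraint-based metabolic models under named
    media; scores competitive ability from mono-, intra- and inter-specific
    growth parameters; quantifies single-cell reproductive success from
    fluorescence-dilution (CUSPER) measurements with limit-of-detection
    handling, division binning, founder-population reconstruction and
    PERMANOVA on population structures; segments bacterial cells in
    two-channel fluorescence images; and ties resource overlap and
    phylogenetic distance to competition outcomes with correlation and
    regression statistics. Includes synthetic-data generators with known
    ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    boot,
    vegan,
    ape,
    jsonlite,
    xml2,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
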