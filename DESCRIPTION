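Package: fungarden
Title: Chemical Gradient Analysis of Layered Fungus-Garden Metabolomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for untargeted LC-MS/MS analysis of spatially deconstructed,
    layered microbial ecosystems such as leaf-cutter ant fungus gardens.
    Builds feature-based molecular networks from MGF fragmentation spectra
    using the modified cosine similarity with mutual top-K edge pruning and
    molecular-family size capping, annotates per-edge precursor mass shifts
    against a catalog of chemical transformations, scores each network edge
    with a log ratio-of-ratios chemical proportionality statistic across
    ordered sample locations, summarises mass-shift frequencies per location
    pair, normalises feature tables against an internal-standard reference
    feature, and exports 3D molecular-cartography tables. A synthetic
    layered-garden generator with known ground truth makes every stage
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
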