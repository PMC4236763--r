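Package: efmdfs
Title: Elementary Flux Mode Enumeration by Depth-First Search and Linear Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive enumeration of elementary flux modes (EFMs) in
    stoichiometric metabolic networks by a depth-first search over inactive
    free fluxes, driven by linear-programming feasibility tests on a
    reduced-row-echelon nullspace basis. Supports direct enumeration of
    constrained EFM subsets (e.g. minimum product yield), divide-and-conquer
    partitioning of the flux cone into exclusive parallel sub-jobs, lossless
    network compression, flux-variability-based model reduction, and a
    brute-force elementarity oracle for verification. Reads models from a
    canonical JSON/TSV reaction format or SBML Level 3.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    quadprog,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
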