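Package: ighrep
Title: Simulation and Analysis of IGH B-Cell Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for immunoglobulin heavy-chain (IGH) repertoire sequencing
    analysis: germline V/D/J/C reference handling, a V(D)J recombination
    simulator with per-read ground truth (segment usage, exonucleolytic
    trimming, palindromic and non-templated junction nucleotides, isotype
    specific somatic hypermutation, power-law clonal expansion, sequencing
    error), a local-alignment read annotator producing AIRR-style
    rearrangement tables (segment calls, productive filtering, CDR-H3
    junction extraction, V-region mutation counting), per-sample repertoire
    summary indices (gene and family usage, Shannon and Simpson diversity,
    CDR-H3 length, normalized Kyte-Doolittle hydrophobicity, somatic
    hypermutation rate, germline index), and rank-based group comparison
    statistics (Mann-Whitney U, Wilcoxon signed rank, Spearman correlation)
    with optional Benjamini-Hochberg adjustment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
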