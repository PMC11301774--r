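Package: massalign
Title: Mass-Coincidence-Aware Alignment and Template-Based Assembly of De
    Novo Peptide Reads
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Template-based assembly of bottom-up de novo sequenced peptides
    into antibody heavy- and light-chain consensus sequences. Implements a
    mass-based local alignment that extends Smith-Waterman with multi-residue
    rotation and isobaric steps to absorb mass-coincidence sequencing errors,
    a survival analysis of mass coincidences among modified residue
    combinations, satellite-ion (w-ion) based isoleucine/leucine
    disambiguation from fragmentation spectra, a binomial sequence-accuracy
    model, readers for common de novo sequencing output formats, a variant
    graph for polyclonal mixtures, and a seeded synthetic-fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Collate:
    'chemistry.R'
    'coincidence.R'
    'alignment.R'
    'assembly.R'
    'xle.R'
    'io_formats.R'
    'variant_graph.R'
    'stats.R'
    'synthetic.R'
    'massalign-package.R'
    'RcppExports.R'
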