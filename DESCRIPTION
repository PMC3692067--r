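Package: profdesign
Title: Evolutionary Profile-Guided Fixed-Backbone Protein Sequence Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fixed-backbone protein sequence design guided by structure-derived
    evolutionary profiles. Given a scaffold structure in PDB format and a library
    of candidate homolog structures, the package builds a position-specific
    log-odds profile from TM-score structural alignments, scores candidate
    sequences with a four-term evolutionary energy (profile match, secondary
    structure, backbone torsion and solvent accessibility agreement) normalized
    as a Z-score against random-sequence baselines, searches sequence space by
    Metropolis Monte Carlo, clusters the decoy pool under a BLOSUM62-derived
    distance, and reports ranked designs with sequence identity, normalized
    relative feature errors and ligand-binding-site conservation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    nnet,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
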