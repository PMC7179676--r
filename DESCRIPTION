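Package: peptevo
Title: Neuropeptide Precursor Processing Grammars and Sequence Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of single-copy neuropeptide precursors.
    Provides a machine-readable registry of per-family prohormone-convertase
    processing grammars (cleavage-flank motifs, peptide location, amidation and
    pyroglutamate expectations) for 21 insect neuropeptide families, rule-based
    excision of mature peptides from precursor sequences, Poisson-corrected
    average evolutionary divergence (AED) with column-bootstrap standard
    errors under pairwise deletion, sequence-logo and consensus statistics with
    ancestral-depth assignment, and a precursor-evolution simulator with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
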