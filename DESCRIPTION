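Package: pa2c
Title: Classification and Comparative Analysis of Plant PA2c-Domain Phospholipase Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for discovering and classifying plant PA2c-domain proteins
    into the canonical secretory phospholipase A2 clades (sPLA2-alpha,
    sPLA2-beta) and the PLA2-like family, with the downstream comparative
    analyses that accompany such surveys: PROSITE-style diagnostic motif
    scanning (calcium-binding loop and catalytic HD dyad variants), a
    signal-peptide hydrophobicity heuristic, cysteine census and
    disulfide-bridge arithmetic, neighbor-joining phylogeny with bootstrap
    monophyly tests, sequence-logo information content, promoter cis-element
    counting, and clade-wise tissue expression summaries. A seeded synthetic
    generator emulates clade-faithful proteins, promoters with planted
    elements, and TPM expression matrices so the whole pipeline is testable
    without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
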