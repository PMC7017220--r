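Package: isoamp
Title: Mining and Characterization of Antimicrobial Peptides from Terrestrial Isopod Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to mine transcript assemblies of terrestrial isopods (Oniscidea) for the
    three antimicrobial peptide families of the group: anti-lipopolysaccharide factors (ALF),
    crustins and the isopod-specific glycine-rich armadillidins. Provides six-frame ORF
    translation, redundancy collapse, an exhaustive Smith-Waterman homology search with
    Karlin-Altschul E-values and reciprocal-best confirmation, rule-based domain and signal
    peptide annotation, crustin type I/II classification, progressive multiple alignment with
    block trimming and physico-chemical consensus, and the full armadillidin mature-peptide
    characterization (GGGX motif scanning, residue over-representation, average mass and
    theoretical isoelectric point). A seeded synthetic transcriptome generator with planted
    precursors supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
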