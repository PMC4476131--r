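Package: serpintron
Title: Intron-Code Classification of Vertebrate Serpin Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies vertebrate serpin (serine proteinase inhibitor) genes
    into the six gene-structure groups V1-V6 defined by conserved intron
    positions and rare indels. Coding-sequence introns are mapped onto the
    mature human alpha-1-antitrypsin reference frame as codon-plus-phase
    codes (e.g. "167a"), matched against per-group signatures, and reported
    together with protein-level diagnostics: the two-residue 173-174 indel,
    reactive-center-loop (RCL) extraction with P1-P1' annotation, and
    C-terminal endoplasmic-reticulum retention motifs. Includes readers for
    GFF3 gene models and FASTA genomes, a global-alignment coordinate
    projector, a seeded synthetic-gene generator for validation, cohort
    summaries, and a tree-concordance (monophyly) checker for newick trees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
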