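Package: tlemine
Title: Mining and Characterization of Tc1-Like DNA Transposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering Tc1-like transposable
    elements (TLEs) in genome assemblies and characterizing their families.
    Candidate transposase loci are found by a seeded six-frame translated
    homology search, extended to complete elements bounded by terminal
    inverted repeats (TIRs) and TA target-site duplications, and families
    are retrieved by exact-terminal-sequence matching. Elements are
    annotated for ORFs and the DDE/D catalytic triad (DD34E and related
    spacing classes), families are dated from consensus divergence under a
    molecular clock, related empty sites are identified and classified,
    transcripts and small RNAs are mapped to element copies, and transposase
    phylogenies are built by bootstrapped neighbor joining. A fully seeded
    synthetic-genome generator plants element families with known ground
    truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite,
    stringi,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
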