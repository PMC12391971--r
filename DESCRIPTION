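Package: carcrac
Title: Scanning and Structural Mapping of CARC/CRAC Cholesterol-Recognition
    Motifs in Protein Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Exhaustive enumeration of CRAC (L/V-X1-5-Y-X1-5-K/R) and CARC
    (K/R-X1-5-Y/F-X1-5-L/V) cholesterol-recognition motifs with variable-length
    spacers on protein sequences, canonical per-site selection, cross-class
    overlap detection and region filtering; mapping of motif instances onto a
    pre-computed multiple sequence alignment to score per-column conservation
    and call per-isoform motif presence; projection of motif residues onto 3D
    coordinates with minimum-distance annotation against named structural
    sites; and seeded synthetic-data generators (motif-implanted sequences,
    alignments with planted presence maps, toy structures with planted
    distances) plus a brute-force oracle so every stage is testable offline.
    Developed around the cytosolic catalytic domains of human transmembrane
    adenylyl cyclases, where such motifs occur near the ATP and forskolin
    binding sites.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    bio3d,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
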