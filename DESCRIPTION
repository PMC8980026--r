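Package: mitocomp
Title: Comparative Mitogenomics of Fish Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated vertebrate
    mitochondrial genomes, built around the Carangidae (jacks and scads)
    and the Indian scad Decapterus russelli as a worked example. Parses
    annotation tables and GenBank flat files into a validated circular
    mitogenome model; computes base composition, AT/GC strand skews,
    intergenic spacers and gene overlaps, start/stop codon classification
    (including incomplete T/TA stops), codon usage and relative synonymous
    codon usage (RSCU) under the vertebrate mitochondrial code, pairwise
    p-distances partitioned by codon position, and Nei-Gojobori Ka/Ks with
    Jukes-Cantor correction; partitions tRNA cloverleaf structures from
    dot-bracket strings, classifies Watson-Crick, G-U wobble and mismatch
    base pairs, and compares wobble frequencies between heavy- and
    light-strand encoded tRNAs; and annotates control regions by bounded
    edit-distance scanning for conserved sequence blocks (CSB-F/E/D/1/2/3),
    palindromic motifs, T-homopolymers and tandem repeats. A seeded
    synthetic-mitogenome generator provides ground-truthed fixtures for
    every analysis stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
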