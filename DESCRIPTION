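Package: allohex
Title: Detecting Allopolyploid Origins from ITS Additivity and Plastid
    Haplotype Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing the allopolyploid origin of a polyploid taxon
    from directly sequenced nuclear ribosomal ITS and chloroplast spacer
    alignments. Detects intraindividual polymorphism recorded as IUPAC
    ambiguity codes, derives diagnostic sites between two parental groups,
    classifies hybrid ribotypes by character-state additivity and the
    direction of concerted-evolution homogenization (including chimeric
    fully homogenized sequences), inventories and scores indels by simple
    indel coding with A/T pseudo-nucleotide recoding, computes
    ambiguity-aware p-distances and group nucleotide diversities, and builds
    statistical-parsimony (TCS-style) haplotype networks with inferred
    intermediate haplotypes under a 95% connection limit. A seeded
    synthetic-data generator emulating two diverged parental clades,
    concerted evolution in hybrids and chloroplast indel variation makes
    every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
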