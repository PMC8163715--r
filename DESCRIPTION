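Package: diagchar
Title: Diagnostic Nucleotide Characters and p-Distances for Molecular Taxonomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Character-based DNA barcoding toolkit for describing cryptic
    species from multiple sequence alignments. Finds single-position and
    combined (adjacent duo) diagnostic nucleotide characters for each species
    against a reference group, computes uncorrected p-distance matrices with
    pairwise deletion (within- and between-species means, nearest-neighbour
    divergences), renders species diagnoses in the style used in taxonomic
    descriptions, classifies unknown sequences against a diagnosis set, and
    simulates seeded alignments with planted diagnostic characters for
    validation. Designed around barcode markers such as mitochondrial COI and
    the nuclear 28S rRNA D1-D2 domains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
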