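Package: lampgen
Title: Design and In-Silico Evaluation of Genus-Specific LAMP Assays from
    Marker-Gene Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for turning metagenome-derived marker genes into
    genus-specific loop-mediated isothermal amplification (LAMP) assays.
    Screens ORF annotation catalogues for orthologue groups unique to a
    taxonomic domain, scores cross-group alignment identity, extracts IUPAC
    degenerate consensus sequences from conserved alignment regions
    (>80 percent per-position identity), designs complete six-to-eight primer
    LAMP sets (F3/B3, FIP/BIP with a TTTT linker, optional loop primers)
    under explicit length, melting-temperature, GC, end-stability, dimer and
    spacing constraints using nearest-neighbour thermodynamics, screens
    primer sets in silico against labelled sequence databases, and places
    targets phylogenetically with Jukes-Cantor distances, neighbour-joining
    and bootstrap. A synthetic-data module generates alignments, ORF
    catalogues and target databases with planted, known structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
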