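Package: alnscope
Title: Pre-Phylogenetic Diagnostics for Multiple Sequence Alignments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Diagnostics for amplicon multiple sequence alignments prior to
    OTU delimitation and phylogenetic inference. Implements gap- and
    ambiguity-aware column Shannon entropy with cumulative and relative
    heterogeneity summaries, alignment treatments that recode terminal gaps
    and excise ambiguously alignable columns, percentage-sequence-identity
    OTU clustering with Chao1/Shannon/rarefaction statistics,
    Kimura-2-parameter substitution saturation profiling, neighbor-joining
    trees with OTU internal distances, and OTU distance-area (IODA/RODA)
    parameters with plot coordinates. Includes a seeded simulator of aligned
    amplicon sets with planted OTU clusters for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    ape,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
biocViews: Alignment, Phylogenetics, Metagenomics, Microbiome, Sequencing
RoxygenNote: 7.3.3
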