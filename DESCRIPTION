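Package: alphasat
Title: Diversity and Organization of Alpha Satellite DNA from
    Restriction-Digest Targeted Sequencing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for characterizing alpha satellite DNA
    families from restriction-digest targeted sequencing of monomer and
    dimer gel bands. Provides in-silico XmnI digestion and a four-stage
    read filter cascade, splitting of dimeric reads into paired left and
    right monomers, alignment-free family discovery by 5-mer composition
    (PCA, Ward clustering and linear discriminant assignment), per-family
    consensus building and identity statistics, duplicate-sequence census
    with an orientation-bias artifact test, left-right monomer association
    analysis, mismatch-aware design of family-discriminating
    oligonucleotide probes, and Kimura 2-parameter neighbor-joining
    phylogenetics with column-resampling bootstrap. A synthetic
    satellite-genome and read simulator with full ground-truth labels
    makes the whole pipeline exercisable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    MASS,
    ape,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
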