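Package: screadkit
Title: Fragment-Geometry Parsing, Read Normalization, and Augmented
    Reference Construction for Single-Cell RNA-Seq Preprocessing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for describing and handling the fragment geometry of
    single-cell RNA-seq libraries. Provides a concise description language
    for the layout of cell barcodes, unique molecular identifiers (UMIs),
    fixed linker (anchor) sequences, and biological sequence within read
    pairs; a streaming normalizer that rewrites reads with complex geometry
    (variable-length barcodes, floating positions located by anchors) into
    a fixed simple layout that any mapper supports; construction of
    augmented transcriptome references (spliced+intron 'splici' and
    spliced+unspliced 'spliceu') with three-column transcript-to-gene maps
    from a genome FASTA and GTF annotation; deterministic index/quant
    command planning with a persisted index manifest that lets
    quantification self-configure; and a JSON workflow-template engine with
    parameter interpolation, required-field checking, and resumable
    execution. A synthetic-fixture generator produces reads with known
    barcode/UMI truth and toy genomes with known intron structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
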