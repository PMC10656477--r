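Package: eletools
Title: Discovery of Transcribed Enhancer-Like Elements from CAGE Data in
    Polyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for annotating transcribed
    enhancer-like elements (ELEs) from stranded CAGE 5'-end count data in
    large, repeat-rich polyploid genomes. Implements CAGE tag-cluster
    calling with replicate-support filtering and sharp/broad shape
    classification, a Bernoulli-emission chromatin-state hidden Markov
    model over binarized 500-bp epigenomic bins with rescue of
    low-confidence gene TSSs, hierarchical TSS annotation (gene TSS,
    intergenic, ELE), distance-decay regulatory-potential linking of ELEs
    to target genes with expression-correlation filtering,
    transposable-element family and subfamily enrichment tests, LTR
    retrotransposon insertion-time dating via Kimura two-parameter
    distances, cross-subgenome homology classification of ELEs through
    collinear-gene syntenic blocks, and a seeded synthetic multi-subgenome
    data generator with planted ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
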