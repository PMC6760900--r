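Package: denovobirth
Title: Screening and Evolutionary Analysis of Lineage-Specific De Novo Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for identifying protein-coding genes that arose de
    novo from intergenic sequence in a focal lineage and for characterising
    their subsequent history. Provides ORF-integrity and phylostratigraphy
    filters backed by Smith-Waterman local alignment with Karlin-Altschul
    E-values, synteny filtering through UCSC chain alignments,
    proteogenomic peptide-uniqueness and ribosome-profiling P-site support,
    Fitch-parsimony tracing of enabler and disabler mutations on a species
    tree with a Jukes-Cantor neutral expectation, estrous-cycle
    cluster-stratified negative-binomial differential expression, and
    exact rank-sum and Fisher tests for litter-interval and infanticide
    phenotypes. Ships seeded simulators that generate ground-truth-labelled
    inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
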