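Package: ngsam
Title: Simulation of Mutagenesis-Aided Sequencing of Repetitive Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the NG-SAM strategy for sequencing repetitive genomic
    regions: error-prone PCR mutagenesis of a repetitive target, serial
    dilution down to a handful of mutant molecules, re-amplification,
    paired-end short-read sequencing of the pooled mutants, de novo assembly
    into per-mutant contigs and reconstruction of the original target by
    majority-vote consensus. PCR genealogies are sampled with a backward
    coalescent method conditional on per-cycle molecule counts; mutations are
    placed on genealogy branches under a general non-reversible (UNREST)
    nucleotide substitution model calibrated against a reported per-cycle
    mutation load. Includes a small de Bruijn assembler and center-star
    aligner so whole experiments run hermetically, plus experiment-grid
    drivers that score reconstruction success across target structures and
    dilution factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    ape,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
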