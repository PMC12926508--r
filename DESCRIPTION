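Package: mamut
Title: Mutation-Accumulation Experiment Analysis for Diploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mutation-accumulation (MA) experiments in
    diploid, clonally propagated organisms such as Daphnia. Calls de novo
    single-nucleotide mutations and small indels from multi-sample variant
    records using a nine-rule hard-filter stack and cross-line ancestral
    consensus, estimates per-line and pooled mutation rates with confidence
    intervals, builds six-type and 96-trinucleotide mutation spectra,
    computes equilibrium GC content under mutation pressure, detects
    loss-of-heterozygosity tracts with a two-state hidden Markov model and
    classifies them as gene conversion or hemizygous deletion from
    standardized coverage, and compares MA-derived mutations with standing
    variation in natural populations. A synthetic MA-experiment generator
    with a planted-event truth table exercises the whole pipeline without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
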