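Package: nullseqgen
Title: Composition-Matched Background DNA Sequences for Motif Enrichment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generates background (null-model) DNA sequence sets whose
    nucleotide composition matches a foreground set, for use in motif
    enrichment analyses. Four background models are provided: exact
    k-let-preserving shuffling of the foreground sequences via a random
    Euler-path construction on the de Bruijn multigraph, the same shuffle
    applied within a sliding window to conserve local composition,
    selection of genomic sequences from a pool binned at 1% GC resolution,
    and selection of genomic sequences whose sliding-window %GC profile
    falls within the foreground's mean +/- SD band. A genome partitioner
    tiles any genome FASTA into fixed-size bins to build background pools,
    and a quality-control module compares foreground and background sets
    with the mean absolute error, Pearson's chi-squared, the G-test and the
    Cressie-Read power divergence over %GC, dinucleotide and length
    distributions. The full IUPAC nucleotide alphabet is supported
    throughout.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, MotifAnnotation, QualityControl
RoxygenNote: 7.3.3
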