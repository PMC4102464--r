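Package: petalseq
Title: De Novo Transcriptome Comparison of Flower-Color Morphs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of a de novo transcriptome comparison
    pipeline for two-morph, two-population mRNA-Seq designs without a
    reference genome. Contigs assembled at multiple kmer values are assigned
    to reference-species genes by score-thresholded reciprocal best hits
    (Karlin-Altschul E-values), collapsed into IUPAC-ambiguity consensus
    sequences with n-padding and an ambiguity-fraction quality gate, and used
    as the mapping reference for a hash-seeded read mapper with a mismatch
    cap. Expression is quantified as RPKM from uniquely mapped reads;
    consistently differentially expressed genes are called with a bounded
    relative-difference statistic and a between-population consistency
    threshold; top-fraction gene sets are tested for GO term enrichment with
    the hypergeometric test and Benjamini-Hochberg correction. Includes
    qRT-PCR comparison arithmetic (delta-delta-Ct, log-log regression),
    genome-size conversion utilities, and a synthetic-data generator that
    emulates short single-end reads from a diverged focal species so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
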