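Package: asmeval
Title: Reference-Free Evaluation and Correction of Long-Read Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates de novo genome assemblies directly against the long
    reads they were built from, without requiring a reference genome. Reads
    are aligned to contigs with minimap2 and the alignments are mined for
    assembly errors: structural errors (>= 50 bp expansions, collapses,
    haplotype switches, and inversions) are detected from CIGAR and split-read
    signals and separated from genetic variants by the ratio of
    error-supporting reads, while small-scale errors (< 50 bp) are called from
    pileup counts with a one-tailed binomial test. An assembly quality value
    (QV) summarises the error load, a targeted correction module patches
    identified errors using local read consensus, an optional reference-based
    mode computes synteny statistics and projects error coordinates, and a
    built-in simulator generates diploid genomes, error-spiked assemblies, and
    long reads to benchmark the whole stack against a known truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings,
    IRanges,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: minimap2 (for read and contig alignment)
Config/testthat/edition: 3
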