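#' Assembly continuity statistics
#'
#' Computes the standard continuity summary of an assembly: number of contigs,
#' total bases, longest and second-longest contig lengths, and N50 (the length
#' of the shortest contig at which the descending cumulative length reaches
#' half of the total; the tie rule is inclusive, i.e. a cumulative sum exactly
#' equal to half the total qualifies). Ambiguous (N) bases count toward contig
#' length: contigs are evaluated as emitted.
#'
#' @param contigs A [Biostrings::DNAStringSet] (e.g. from [read_fasta()]).
#' @param min_len Contigs shorter than this are excluded from all statistics.
#'   The default keeps everything; evaluation does not silently drop short
#'   contigs.
#' @return An object of class `assembly_stats`: a list with `n_contigs`,
#'   `total_bases`, `longest`, `second_longest`, `n50`, and `min_contig_filter`.
#' @examples
#' ctg <- Biostrings::DNAStringSet(c(a = "ACGTACGT", b = "ACGT"))
#' contig_stats(ctg)
#' @export
contig_stats <- function(contigs, min_len = 0L) {
  stopifnot(is_scalar_number(min_len), min_len >= 0)
  w <- as.numeric(Biostrings::width(contigs))
  w <- w[w >= min_len]
  if (length(w) == 0) {
    warning("all contigs removed by min_len filter; statistics are zero")
    return(structure(list(n_contigs = 0L, total_bases = 0, longest = 0L,
                          second_longest = 0L, n50 = 0L,
                          min_contig_filter = as.integer(min_len)),
                     class = "assembly_stats"))
  }
  sw <- sort(w, decreasing = TRUE)
  structure(list(
    n_contigs = length(w),
    total_bases = sum(w),
    longest = as.integer(sw[1]),
    second_longest = as.integer(if (length(sw) > 1) sw[2] else 0L),
    n50 = weighted_nxx(w),
    min_contig_filter = as.integer(min_len)
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly continuity\n")
  cat(sprintf("  contigs:         %d\n", x$n_contigs))
  cat(sprintf("  total bases:     %.0f\n", x$total_bases))
  cat(sprintf("  longest:         %d\n", x$longest))
  cat(sprintf("  second longest:  %d\n", x$second_longest))
  cat(sprintf("  N50:             %d\n", x$n50))
  invisible(x)
}
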