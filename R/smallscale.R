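## Small-scale assembly errors (< 50 bp): pileup counting, the 20% support
## pre-filter, and a one-tailed binomial test that separates consensus errors
## (expected in ~100% of reads) from heterozygous variants (~50%).

#' Pileup counts for one contig
#'
#' Tallies, for every contig position, the number of spanning reads (reads
#' whose alignment covers the position with an aligned or deleted base), the
#' count of each read base, the count of reads deleting the position, and the
#' count of reads with an insertion anchored immediately after the position.
#' Indel runs of `small_max` bp or more are structural-scale events and are
#' excluded from the indel tallies (their columns still count as spanned).
#' Secondary alignments and records without sequence are skipped.
#'
#' @param segments Segment table from [parse_alignments()] restricted to one
#'   contig.
#' @param contig The contig sequence (character or [Biostrings::DNAString]).
#' @param small_max Upper size bound (exclusive) for small-scale indels.
#' @return An object of class `asmeval_pileup`: a list with `depth`, a 4-row
#'   `bases` count matrix (A, C, G, T), `del`, `ins` (integer vectors along
#'   the contig), and the contig itself.
#' @export
pileup <- function(segments, contig, small_max = 50L) {
  contig <- as.character(contig)
  seg <- segments[!segments$is_secondary & !is.na(segments$seq) &
                    segments$seq != "*", , drop = FALSE]
  pc <- .pileup_core(contig, as.integer(seg$contig_start), seg$cigar, seg$seq,
                     as.integer(small_max))
  rownames(pc$bases) <- c("A", "C", "G", "T")
  structure(list(depth = pc$depth, bases = pc$bases, del = pc$del,
                 ins = pc$ins, contig = contig, small_max = small_max),
            class = "asmeval_pileup")
}

#' Tabular view of pileup columns
#'
#' @param x An `asmeval_pileup`.
#' @param positions 0-based positions to extract (default: all covered).
#' @param ... Unused.
#' @return A `data.frame` with one row per position: `pos` (0-based),
#'   `ref_base`, `depth`, per-base counts, `del`, `ins`.
#' @export
as.data.frame.asmeval_pileup <- function(x, positions = NULL, ...) {
  if (is.null(positions)) positions <- which(x$depth > 0) - 1L
  i <- positions + 1L
  data.frame(pos = positions,
             ref_base = substring(x$contig, i, i),
             depth = x$depth[i],
             A = x$bases["A", i], C = x$bases["C", i],
             G = x$bases["G", i], T = x$bases["T", i],
             del = x$del[i], ins = x$ins[i],
             stringsAsFactors = FALSE)
}

#' Candidate small-scale errors from pileup counts
#'
#' For every sufficiently covered column the single most-supported alternative
#' event (a non-contig base, an insertion, or a deletion) becomes a candidate
#' iff its support fraction reaches `min_fraction` (inclusive: exactly 20%
#' support is retained). Runs of consecutive deletion candidates are merged
#' into one multi-base candidate. Columns below `min_depth` spanning reads are
#' uncallable and skipped.
#'
#' @param pu An `asmeval_pileup` from [pileup()].
#' @param min_fraction Minimum support fraction for a candidate.
#' @param min_depth Minimum spanning-read depth for a callable column.
#' @return A `data.frame` with `pos` (0-based), `event` (`sub`, `ins`, `del`),
#'   `size`, `n_reads`, `n_supp`, `alt_base` (substitutions only).
#' @export
candidate_small_errors <- function(pu, min_fraction = 0.2, min_depth = 5L) {
  depth <- pu$depth
  L <- length(depth)
  callable <- depth >= min_depth
  ref_idx <- match(strsplit(pu$contig, "", fixed = TRUE)[[1]],
                   c("A", "C", "G", "T"))
  alt_bases <- pu$bases
  sel <- !is.na(ref_idx)
  if (any(sel)) {
    idx <- cbind(ref_idx[sel], which(sel))
    alt_bases[idx] <- 0L  # zero out the contig base's own count
  }
  top_base <- matrixStats_colMax(alt_bases)
  top_base_which <- max.col(t(alt_bases), ties.method = "first")
  cnt <- cbind(sub = top_base, ins = pu$ins, del = pu$del)
  best <- max.col(cnt, ties.method = "first")
  best_cnt <- cnt[cbind(seq_len(L), best)]
  keep <- callable & best_cnt >= min_fraction * depth & best_cnt > 0
  if (!any(keep)) {
    return(data.frame(pos = integer(), event = character(), size = integer(),
                      n_reads = integer(), n_supp = integer(),
                      alt_base = character(), stringsAsFactors = FALSE))
  }
  pos <- which(keep)
  ev <- c("sub", "ins", "del")[best[pos]]
  out <- data.frame(pos = pos - 1L, event = ev, size = 1L,
                    n_reads = depth[pos], n_supp = best_cnt[pos],
                    alt_base = ifelse(ev == "sub",
                                      c("A", "C", "G", "T")[top_base_which[pos]],
                                      NA_character_),
                    stringsAsFactors = FALSE)
  merge_del_runs(out)
}

matrixStats_colMax <- function(m) {
  ## column maxima of a 4 x L integer matrix without extra dependencies
  pmax(m[1, ], m[2, ], m[3, ], m[4, ])
}

## Consecutive deletion candidates are one multi-base deletion event: merge
## them, keeping the run's median support.
merge_del_runs <- function(cand) {
  is_del <- cand$event == "del"
  if (sum(is_del) < 2) return(cand)
  d <- cand[is_del, , drop = FALSE]
  run <- cumsum(c(TRUE, diff(d$pos) != 1L))
  merged <- do.call(rbind, lapply(split(d, run), function(g) {
    data.frame(pos = g$pos[1], event = "del", size = nrow(g),
               n_reads = as.integer(round(stats::median(g$n_reads))),
               n_supp = as.integer(round(stats::median(g$n_supp))),
               alt_base = NA_character_, stringsAsFactors = FALSE)
  }))
  out <- rbind(cand[!is_del, , drop = FALSE], merged)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-tailed binomial upper-tail probability
#'
#' Probability of observing `n_supp` or more error-supporting reads among
#' `n_reads` trials when each read supports with probability `p`:
#' `sum_{i = n_supp}^{n_reads} C(n_reads, i) p^i (1-p)^(n_reads - i)`.
#' Under the null hypothesis the locus is a heterozygous variant, so `p` is
#' the chance that a read drawn from either haplotype shows the alternative
#' allele (0.5 for accurate reads, lower for noisy reads).
#'
#' @param n_supp Number of supporting reads (vectorised).
#' @param n_reads Number of spanning reads (trials).
#' @param p Per-read support probability under the null.
#' @return Upper-tail p-value(s).
#' @examples
#' binomial_pvalue(10, 10, 0.5)  # 0.5^10
#' binomial_pvalue(2, 4, 0.5)    # 11/16
#' @export
binomial_pvalue <- function(n_supp, n_reads, p) {
  if (any(!is.finite(n_supp)) || any(!is.finite(n_reads)))
    stop("n_supp and n_reads must be finite")
  if (any(n_supp < 0) || any(n_reads < 0) || any(n_supp > n_reads))
    stop("need 0 <= n_supp <= n_reads")
  if (any(p <= 0) || any(p >= 1)) stop("need 0 < p < 1")
  stats::pbinom(n_supp - 1, n_reads, p, lower.tail = FALSE)
}

#' Datatype-specific binomial-test settings
#'
#' HiFi reads are accurate, so a read from the error-free haplotype of a
#' heterozygous variant shows the alternative allele with probability ~0.5
#' and the null uses p = 0.5 with a strict 0.01 significance cut. CLR and
#' Nanopore reads carry 15-20% sequencing error, which erodes per-read
#' support, so the null uses p = 0.4 and a 0.05 cut.
#'
#' @param datatype One of `"hifi"`, `"clr"`, `"nano"`.
#' @return List with `p_err` and `alpha`.
#' @export
small_error_test_params <- function(datatype = c("hifi", "clr", "nano")) {
  datatype <- match.arg(datatype)
  if (datatype == "hifi") list(p_err = 0.5, alpha = 0.01)
  else list(p_err = 0.4, alpha = 0.05)
}

#' Call small-scale errors from candidates
#'
#' Applies the one-tailed binomial test to each candidate and keeps those with
#' p-value below the datatype threshold. Event types map to error kinds from
#' the contig's point of view: an alternative read base is a
#' `BaseSubstitution`; an insertion in the reads means the contig is missing
#' sequence (`SmallCollapse`); a deletion in the reads means the contig
#' carries extra sequence (`SmallExpansion`).
#'
#' @param candidates Candidate table from [candidate_small_errors()].
#' @param datatype Sequencing chemistry (sets `p` and the significance cut).
#' @param p_err,alpha Override the datatype defaults.
#' @return A `data.frame` of class `small_scale_errors` with `pos`, `kind`,
#'   `size`, `n_reads`, `n_supp`, `support_fraction`, `p_value`, `alt_base`.
#' @export
call_small_errors <- function(candidates, datatype = c("hifi", "clr", "nano"),
                              p_err = NULL, alpha = NULL) {
  tp <- small_error_test_params(match.arg(datatype))
  p_err <- p_err %||% tp$p_err
  alpha <- alpha %||% tp$alpha
  if (nrow(candidates) == 0) {
    out <- data.frame(pos = integer(), kind = character(), size = integer(),
                      n_reads = integer(), n_supp = integer(),
                      support_fraction = numeric(), p_value = numeric(),
                      alt_base = character(), stringsAsFactors = FALSE)
    class(out) <- c("small_scale_errors", "data.frame")
    return(out)
  }
  pv <- binomial_pvalue(candidates$n_supp, candidates$n_reads, p_err)
  keep <- pv < alpha
  out <- candidates[keep, , drop = FALSE]
  out$kind <- c(sub = "BaseSubstitution", ins = "SmallCollapse",
                del = "SmallExpansion")[out$event]
  out$support_fraction <- out$n_supp / out$n_reads
  out$p_value <- pv[keep]
  out$event <- NULL
  out <- out[, c("pos", "kind", "size", "n_reads", "n_supp",
                 "support_fraction", "p_value", "alt_base")]
  rownames(out) <- NULL
  class(out) <- c("small_scale_errors", "data.frame")
  out
}

#' Detect small-scale errors on one contig
#'
#' Driver: pileup, candidate pre-filter, binomial test, and allele
#' annotation. For insertion candidates a second pass over the alignments
#' collects the inserted sequences at the called anchors and records the
#' majority string as the read allele; substitutions take the majority
#' alternative base; deletions take the deleted contig bases.
#'
#' @param segments Segment table restricted to one contig.
#' @param contig Contig sequence (character or DNAString).
#' @param datatype Sequencing chemistry.
#' @param params Parameter list from [eval_params()].
#' @return A `small_scale_errors` data.frame with `contig_allele` and
#'   `read_allele` columns.
#' @export
detect_small_errors <- function(segments, contig,
                                datatype = c("hifi", "clr", "nano"),
                                params = eval_params(datatype)) {
  datatype <- match.arg(datatype)
  contig <- as.character(contig)
  pu <- pileup(segments, contig, small_max = params$min_structural_size)
  cand <- candidate_small_errors(pu, min_fraction = params$min_fraction,
                                 min_depth = params$min_depth)
  calls <- call_small_errors(cand, datatype,
                             p_err = params$p_err, alpha = params$alpha)
  annotate_small_alleles(calls, segments, contig, params)
}

annotate_small_alleles <- function(calls, segments, contig, params) {
  n <- nrow(calls)
  calls$contig_allele <- character(n)
  calls$read_allele <- character(n)
  if (n == 0) return(calls)
  base_at <- function(pos, len = 1L) substring(contig, pos + 1L, pos + len)
  sub <- which(calls$kind == "BaseSubstitution")
  if (length(sub) > 0) {
    calls$contig_allele[sub] <- base_at(calls$pos[sub])
    calls$read_allele[sub] <- calls$alt_base[sub]
  }
  del <- which(calls$kind == "SmallExpansion")
  if (length(del) > 0) {
    calls$contig_allele[del] <- base_at(calls$pos[del], calls$size[del])
    calls$read_allele[del] <- "-"
  }
  ins <- which(calls$kind == "SmallCollapse")
  if (length(ins) > 0) {
    seg <- segments[!segments$is_secondary & !is.na(segments$seq) &
                      segments$seq != "*", , drop = FALSE]
    ev <- .insertion_events(as.integer(seg$contig_start), seg$cigar, seg$seq,
                            sort(unique(as.integer(calls$pos[ins]))),
                            as.integer(params$min_structural_size))
    for (i in ins) {
      seqs <- ev$seq[ev$pos == calls$pos[i]]
      calls$contig_allele[i] <- "-"
      calls$read_allele[i] <- if (length(seqs) > 0)
        names(sort(table(seqs), decreasing = TRUE))[1] else "N"
      calls$size[i] <- nchar(calls$read_allele[i])
    }
  }
  calls
}
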