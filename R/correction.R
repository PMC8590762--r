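## Targeted assembly error correction: direct substitution for small-scale
## errors, local read-consensus patches for structural errors.

#' Build patches correcting small-scale errors
#'
#' Substitutions replace the contig base with the majority read base; a small
#' expansion (extra contig sequence) removes the affected bases; a small
#' collapse (missing contig sequence) inserts the majority read allele after
#' its anchor. Overlapping errors keep the one with the lower p-value.
#'
#' @param contigs [Biostrings::DNAStringSet].
#' @param small Named per-contig list (or single data.frame with `contig_id`)
#'   of `small_scale_errors`.
#' @return A `data.frame` of patches (`contig_id`, `start`, `end`,
#'   `replacement`, `source`, `provenance`, `n_support`, `p_value`).
#' @export
small_error_patches <- function(contigs, small) {
  s <- bind_small(small)
  if (nrow(s) == 0) return(empty_patches())
  start <- ifelse(s$kind == "SmallCollapse", s$pos + 1L, s$pos)
  end <- ifelse(s$kind == "SmallCollapse", s$pos + 1L,
                ifelse(s$kind == "SmallExpansion", s$pos + s$size, s$pos + 1L))
  repl <- ifelse(s$kind == "SmallExpansion", "", s$read_allele)
  data.frame(contig_id = s$contig_id, start = start, end = end,
             replacement = repl, source = "substitution",
             provenance = paste0(s$kind, "@", s$contig_id, ":", s$pos),
             n_support = s$n_supp, p_value = s$p_value,
             stringsAsFactors = FALSE)
}

empty_patches <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             replacement = character(), source = character(),
             provenance = character(), n_support = integer(),
             p_value = numeric(), stringsAsFactors = FALSE)
}

#' Apply small-scale corrections to contigs
#'
#' @inheritParams small_error_patches
#' @return List with corrected `contigs` and the applied `patches` log.
#' @export
correct_small <- function(contigs, small) {
  apply_patches(contigs, small_error_patches(contigs, small))
}

#' Collect the reads supporting a structural error
#'
#' Returns the alignment segments of the error-supporting reads overlapping
#' the error locus padded by `flank`. For a haplotype switch only the reads of
#' the better-supported side are returned (ties pick the expansion side): the
#' goal of the correction is to reconstruct one haplotype, not a blend. Only
#' reads anchored across the whole patch window (both flanks aligned in one
#' segment) can be used for consensus building, which keeps reads from other
#' repeat units out of the local assembly.
#'
#' @param error One row of a `structural_errors` data.frame.
#' @param segments Segment table from [parse_alignments()].
#' @param flank Padding in bp around the locus.
#' @param min_support Minimum usable reads; fewer marks the error
#'   uncorrectable (`NULL` return).
#' @return Segment rows of the selected reads, or `NULL`.
#' @export
collect_error_reads <- function(error, segments, flank = 5000L,
                                min_support = 3L) {
  ids <- if (error$kind == "HaplotypeSwitch") {
    ne <- length(error$reads_exp[[1]]); nc <- length(error$reads_col[[1]])
    if (ne >= nc) error$reads_exp[[1]] else error$reads_col[[1]]
  } else error$reads[[1]]
  seg <- segments[!segments$is_secondary &
                    segments$read_id %in% ids &
                    segments$contig_id == error$contig_id &
                    segments$contig_start <= error$end + flank &
                    segments$contig_end >= error$start - flank, , drop = FALSE]
  if (length(unique(seg$read_id)) < min_support) return(NULL)
  seg
}

#' Local consensus from a set of read subsequences
#'
#' Built-in local reassembly engine: a greedy star alignment of all sequences
#' against a centre sequence (the one of median length) followed by
#' column-majority consensus, including majority-voted insertions relative to
#' the centre. An external assembler can be plugged in via `engine`.
#'
#' @param seqs Character vector of read subsequences spanning the same locus.
#' @param engine Optional function `(seqs) -> character(1)` replacing the
#'   built-in consensus.
#' @param max_reads Sequences used (deepest loci are downsampled
#'   deterministically by taking the first `max_reads` after sorting).
#' @param min_reads Fewer sequences than this aborts (`NULL` return).
#' @return Consensus sequence (character scalar), or `NULL` if no consensus
#'   could be built.
#' @export
local_reassemble <- function(seqs, engine = NULL, max_reads = 15L,
                             min_reads = 3L) {
  seqs <- seqs[!is.na(seqs) & nzchar(seqs)]
  if (length(seqs) < min_reads) return(NULL)
  if (!is.null(engine)) return(engine(seqs))
  if (length(seqs) > max_reads) seqs <- sort(seqs)[seq_len(max_reads)]
  consensus_star(seqs)
}

consensus_star <- function(seqs) {
  n <- length(seqs)
  center_i <- order(abs(nchar(seqs) - stats::median(nchar(seqs))))[1]
  center <- seqs[center_i]
  others <- seqs[-center_i]
  nc <- nchar(center)
  counts <- matrix(0L, nrow = 5, ncol = nc,
                   dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  cb <- strsplit(center, "", fixed = TRUE)[[1]]
  idx <- match(cb, rownames(counts))
  ok <- !is.na(idx)
  counts[cbind(idx[ok], which(ok))] <- 1L
  ins_store <- vector("list", nc + 1)  # insertions before centre pos c+1

  if (length(others) > 0) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(others), Biostrings::DNAString(center),
      type = "global", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 2)
    pat <- as.character(Biostrings::alignedPattern(aln))
    sub <- as.character(Biostrings::alignedSubject(aln))
    for (k in seq_along(pat)) {
      p <- strsplit(pat[k], "", fixed = TRUE)[[1]]
      s <- strsplit(sub[k], "", fixed = TRUE)[[1]]
      is_base <- s != "-"
      cpos <- cumsum(is_base)           # centre coordinate per column
      bi <- match(p[is_base], rownames(counts))
      cp <- cpos[is_base]
      ok <- !is.na(bi)
      if (any(ok)) {
        tab <- cbind(bi[ok], cp[ok])
        counts[tab] <- counts[tab] + 1L
      }
      gap <- which(!is_base)
      if (length(gap) > 0) {
        run <- split(gap, cumsum(c(TRUE, diff(gap) != 1L)))
        for (r in run) {
          at <- cpos[r[1]] + 1L          # insertion before centre pos `at`
          insseq <- paste(p[r][p[r] != "-"], collapse = "")
          if (nzchar(insseq))
            ins_store[[at]] <- c(ins_store[[at]], insseq)
        }
      }
    }
  }

  maj <- rownames(counts)[max.col(t(counts), ties.method = "first")]
  pieces <- character(0)
  for (c0 in seq_len(nc + 1)) {
    insv <- ins_store[[c0]]
    if (!is.null(insv) && length(insv) > n / 2) {
      pieces <- c(pieces, names(sort(table(insv), decreasing = TRUE))[1])
    }
    if (c0 <= nc && maj[c0] != "-") pieces <- c(pieces, maj[c0])
  }
  paste(pieces, collapse = "")
}

#' Build a patch correcting one structural error
#'
#' Inversions are corrected directly by reverse-complementing the called
#' interval. Expansions, collapses, and haplotype switches are corrected by
#' local reassembly: each supporting read's subsequence spanning the patch
#' window (error interval padded by `anchor` on both sides, boundaries mapped
#' through the read's CIGAR) is extracted, a consensus is built with
#' [local_reassemble()], its flanks are verified against the contig, and the
#' consensus replaces the window.
#'
#' @param error One `structural_errors` row.
#' @param contig Contig sequence (character).
#' @param segments Segment table for the error's contig.
#' @param params [eval_params()] list (uses `flank`, `anchor`,
#'   `max_consensus_reads`, `min_support`).
#' @param engine Optional external consensus engine (see
#'   [local_reassemble()]).
#' @return A one-row patch data.frame, or `NULL` if uncorrectable.
#' @export
structural_error_patch <- function(error, contig, segments,
                                   params = eval_params("hifi"),
                                   engine = NULL) {
  L <- nchar(contig)
  prov <- paste0(error$kind, "@", error$contig_id, ":", error$start)
  if (error$kind == "Inversion") {
    s <- max(0L, error$start); e <- min(L, error$end)
    if (e - s < 1) return(NULL)
    return(data.frame(contig_id = error$contig_id, start = s, end = e,
                      replacement = revcomp_chr(substring(contig, s + 1L, e)),
                      source = "inversion_flip", provenance = prov,
                      n_support = error$n_support, p_value = NA_real_,
                      stringsAsFactors = FALSE))
  }
  ws <- max(0L, error$start - params$anchor)
  we <- min(L, error$end + params$anchor)
  seg <- collect_error_reads(error, segments, flank = params$flank,
                             min_support = params$min_support)
  if (is.null(seg)) return(NULL)
  span <- seg[seg$contig_start <= ws & seg$contig_end >= we &
                !is.na(seg$seq) & seg$seq != "*", , drop = FALSE]
  if (nrow(span) > 0) span <- span[!duplicated(span$read_id), , drop = FALSE]
  if (nrow(span) < params$min_support) return(NULL)
  windows <- vapply(seq_len(nrow(span)), function(i) {
    off <- .contig_to_seq_offset(span$cigar[i],
                                 as.integer(span$contig_start[i]),
                                 as.integer(c(ws, we - 1L)))
    if (any(off < 0)) return(NA_character_)
    substring(span$seq[i], off[1] + 1L, off[2] + 1L)
  }, character(1))
  cons <- local_reassemble(windows, engine = engine,
                           max_reads = params$max_consensus_reads,
                           min_reads = params$min_support)
  if (is.null(cons) || nchar(cons) < 2 * 0.5 * params$anchor) return(NULL)
  if (!flanks_match(cons, contig, ws, we)) return(NULL)
  data.frame(contig_id = error$contig_id, start = ws, end = we,
             replacement = cons, source = "local_assembly", provenance = prov,
             n_support = error$n_support, p_value = NA_real_,
             stringsAsFactors = FALSE)
}

## The consensus must anchor to the contig on both sides of the error;
## otherwise the correction is abandoned and the original retained.
flanks_match <- function(cons, contig, ws, we, k = 200L, min_pid = 75) {
  k <- min(k, nchar(cons) %/% 2)
  if (k < 20) return(FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = FALSE)
  pid_of <- function(a, b) {
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                         Biostrings::DNAString(b),
                                         type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 4, gapExtension = 2)
    Biostrings::pid(aln)
  }
  left <- substring(contig, ws + 1L, min(ws + k, nchar(contig)))
  right <- substring(contig, max(1L, we - k + 1L), we)
  pid_of(substring(cons, 1L, k), left) >= min_pid &&
    pid_of(substring(cons, nchar(cons) - k + 1L, nchar(cons)), right) >= min_pid
}

#' Apply patches to contigs
#'
#' Patches are applied per contig in descending coordinate order so earlier
#' coordinates stay valid. Overlapping patches keep the better-supported one
#' (higher `n_support`, then lower `p_value`); the loser is logged as
#' skipped.
#'
#' @param contigs [Biostrings::DNAStringSet].
#' @param patches Patch table (see [small_error_patches()]).
#' @return List with corrected `contigs`, the `patches` log (applied, with
#'   original spans), and `skipped` (conflicting patches).
#' @export
apply_patches <- function(contigs, patches) {
  if (nrow(patches) == 0)
    return(list(contigs = contigs, patches = empty_patches(),
                skipped = empty_patches()))
  out <- as.character(contigs)
  names(out) <- seq_names(contigs)
  applied <- list(); skipped <- list()
  for (cid in unique(patches$contig_id)) {
    p <- patches[patches$contig_id == cid, , drop = FALSE]
    ord <- order(p$start, p$end,
                 -replace(p$n_support, is.na(p$n_support), 0L))
    p <- p[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(p))
    last_end <- -1L
    for (i in seq_len(nrow(p))) {
      if (p$start[i] < last_end) {
        ## overlap with previous kept patch: keep the better-supported one
        prev <- max(which(keep[seq_len(i - 1)]))
        better_i <- (p$n_support[i] %||% 0) > (p$n_support[prev] %||% 0) ||
          (identical(p$n_support[i], p$n_support[prev]) &&
             isTRUE(p$p_value[i] < p$p_value[prev]))
        if (better_i) { keep[prev] <- FALSE; last_end <- max(last_end, p$end[i]) }
        else keep[i] <- FALSE
        next
      }
      last_end <- max(last_end, p$end[i])
    }
    skipped[[cid]] <- p[!keep, , drop = FALSE]
    p <- p[keep, , drop = FALSE]
    seqc <- out[[cid]]
    for (i in rev(seq_len(nrow(p)))) {
      seqc <- paste0(substring(seqc, 1L, p$start[i]),
                     p$replacement[i],
                     substring(seqc, p$end[i] + 1L, nchar(seqc)))
    }
    out[[cid]] <- seqc
    applied[[cid]] <- p
  }
  list(contigs = Biostrings::DNAStringSet(out),
       patches = do.call(rbind, c(applied, list(empty_patches()))),
       skipped = do.call(rbind, c(skipped, list(empty_patches()))))
}

#' Correct an evaluated assembly
#'
#' One correction round: builds local-consensus patches for every structural
#' error and substitution patches for every small-scale error (small errors
#' inside a structural patch window are covered by the window and dropped),
#' then applies them. Uncorrectable structural errors are retained in the
#' output assembly and reported, never silently dropped.
#'
#' @param contigs Assembly FASTA path or [Biostrings::DNAStringSet].
#' @param evaluation An `asm_evaluation` (run with `keep_segments = TRUE`, or
#'   pass `segments`).
#' @param segments Segment table (defaults to `evaluation$segments`).
#' @param engine Optional external consensus engine.
#' @param out_fasta Optional path for the corrected assembly FASTA.
#' @param patch_log Optional path for a patches TSV log.
#' @return List with `contigs` (corrected), `patches`, `skipped`, and
#'   `uncorrectable` (structural errors left in place).
#' @export
correct_assembly <- function(contigs, evaluation, segments = NULL,
                             engine = NULL, out_fasta = NULL,
                             patch_log = NULL) {
  if (!inherits(contigs, "DNAStringSet")) contigs <- read_fasta(contigs)
  segments <- segments %||% evaluation$segments
  if (is.null(segments))
    stop("no alignment segments available; rerun evaluate_assembly() with ",
         "keep_segments = TRUE or pass segments=")
  params <- evaluation$params
  structural <- evaluation$structural
  spatches <- list(); uncorrectable <- list()
  for (i in seq_len(nrow(structural))) {
    err <- structural[i, , drop = FALSE]
    cid <- err$contig_id
    seg <- segments[segments$contig_id == cid, , drop = FALSE]
    p <- structural_error_patch(err, as.character(contigs[[cid]]), seg,
                                params = params, engine = engine)
    if (is.null(p)) uncorrectable[[length(uncorrectable) + 1]] <- err
    else spatches[[length(spatches) + 1]] <- p
  }
  spatch <- do.call(rbind, c(spatches, list(empty_patches())))
  small_p <- small_error_patches(contigs, evaluation$small)
  if (nrow(small_p) > 0 && nrow(spatch) > 0) {
    inside <- vapply(seq_len(nrow(small_p)), function(i) {
      any(spatch$contig_id == small_p$contig_id[i] &
            spatch$start <= small_p$start[i] &
            spatch$end >= small_p$end[i])
    }, logical(1))
    small_p <- small_p[!inside, , drop = FALSE]
  }
  res <- apply_patches(contigs, rbind(spatch, small_p))
  res$uncorrectable <- do.call(rbind, c(uncorrectable, list(NULL)))
  if (!is.null(out_fasta)) write_fasta(res$contigs, out_fasta)
  if (!is.null(patch_log))
    write.table(res$patches, patch_log, sep = "\t", quote = FALSE,
                row.names = FALSE)
  res
}
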