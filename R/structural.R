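## Structural assembly errors (>= 50 bp): raw signal extraction from CIGARs and
## split reads, adaptive-window clustering, haplotype-switch merging, and the
## variant-vs-error support-ratio filter.

empty_signals <- function() {
  data.frame(kind = character(), contig_id = character(), pos = integer(),
             size = integer(), read_id = character(), mapq = integer(),
             stringsAsFactors = FALSE)
}

#' Extract raw structural-error signals from alignment segments
#'
#' Scans every non-secondary alignment for three signal types: a deletion run
#' (`D`) of at least `min_size` in a read alignment is an expansion signal
#' (the contig carries sequence the read skips); an insertion run (`I`) is a
#' collapse signal (the read carries sequence the contig lacks); split
#' alignments of one read on one contig yield expansion/collapse signals when
#' the contig-coordinate gap and read-coordinate gap disagree by at least
#' `min_size`, and inversion signals when a read aligns in three or more
#' segments with a strand flip (the minority-strand segment is the inverted
#' block; two-segment flips are ambiguous about which side is inverted and are
#' ignored).
#'
#' @param segments Segment table from [parse_alignments()] (any number of
#'   reads; grouping by read happens internally).
#' @param min_size Minimum signal size in bp (the structural-error class
#'   boundary).
#' @return A `data.frame` with columns `kind` (`expansion`, `collapse`,
#'   `inversion`), `contig_id`, `pos` (0-based left breakpoint), `size`,
#'   `read_id`, `mapq`.
#' @export
extract_signals <- function(segments, min_size = 50L) {
  seg <- segments[!segments$is_secondary, , drop = FALSE]
  if (nrow(seg) == 0) return(empty_signals())

  with_cig <- seg[!is.na(seg$cigar), , drop = FALSE]
  ind <- if (nrow(with_cig) > 0) {
    .cigar_indels(with_cig$cigar, as.integer(with_cig$contig_start),
                  as.integer(min_size))
  } else data.frame(seg = integer(), kind = character(), pos = integer(),
                    size = integer())
  cig_sig <- if (nrow(ind) > 0) {
    data.frame(kind = ind$kind, contig_id = with_cig$contig_id[ind$seg],
               pos = ind$pos, size = ind$size,
               read_id = with_cig$read_id[ind$seg],
               mapq = with_cig$mapq[ind$seg], stringsAsFactors = FALSE)
  } else empty_signals()

  split_ids <- unique(seg$read_id[duplicated(seg$read_id)])
  split_sig <- if (length(split_ids) > 0) {
    sseg <- seg[seg$read_id %in% split_ids, , drop = FALSE]
    groups <- split(sseg, list(sseg$read_id, sseg$contig_id), drop = TRUE)
    out <- lapply(groups, split_read_signals, min_size = min_size)
    do.call(rbind, c(out, list(empty_signals())))
  } else empty_signals()

  res <- rbind(cig_sig, split_sig)
  rownames(res) <- NULL
  res
}

## Signals from the split segments of one read on one contig.
split_read_signals <- function(g, min_size) {
  if (nrow(g) < 2) return(empty_signals())
  g <- g[order(g$read_start), , drop = FALSE]
  out <- list()

  ## gap/overlap disagreement between consecutive same-strand segments
  for (i in seq_len(nrow(g) - 1)) {
    a <- g[i, ]; b <- g[i + 1, ]
    if (a$strand != b$strand) next
    gap_r <- b$read_start - a$read_end
    if (a$strand == "+") {
      gap_c <- b$contig_start - a$contig_end
      pos <- a$contig_end
    } else {
      gap_c <- a$contig_start - b$contig_end
      pos <- b$contig_end
    }
    d <- gap_c - gap_r
    mq <- min(a$mapq, b$mapq)
    if (d >= min_size) {
      out[[length(out) + 1]] <- data.frame(
        kind = "expansion", contig_id = a$contig_id, pos = pos, size = d,
        read_id = a$read_id, mapq = mq, stringsAsFactors = FALSE)
    } else if (-d >= min_size) {
      out[[length(out) + 1]] <- data.frame(
        kind = "collapse", contig_id = a$contig_id, pos = pos, size = -d,
        read_id = a$read_id, mapq = mq, stringsAsFactors = FALSE)
    }
  }

  ## inversion: minority-strand block among >= 3 segments
  if (nrow(g) >= 3 && length(unique(g$strand)) > 1) {
    span <- g$contig_end - g$contig_start
    plus <- sum(span[g$strand == "+"])
    minus <- sum(span[g$strand == "-"])
    minority <- if (plus >= minus) "-" else "+"
    inv <- g[g$strand == minority & span >= min_size, , drop = FALSE]
    if (nrow(inv) > 0) {
      out[[length(out) + 1]] <- data.frame(
        kind = "inversion", contig_id = inv$contig_id, pos = inv$contig_start,
        size = inv$contig_end - inv$contig_start, read_id = inv$read_id,
        mapq = inv$mapq, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(empty_signals())))
}

empty_clusters <- function() {
  data.frame(kind = character(), contig_id = character(), start = integer(),
             end = integer(), size_estimate = integer(), size_exp = integer(),
             size_col = integer(), n_support = integer(), n_signals = integer(),
             mean_mapq = numeric(), reads = I(list()), reads_exp = I(list()),
             reads_col = I(list()), stringsAsFactors = FALSE)
}

#' Cluster raw structural signals with an adaptive window
#'
#' Greedy left-to-right clustering, run independently per signal type and
#' contig on position-sorted signals: a signal joins the open cluster if its
#' position is within `max(base_window, repeat_tolerance_factor *
#' median cluster size)` of the cluster's rightmost member, otherwise a new
#' cluster opens. Scaling the window with the cluster's size estimate tolerates
#' the larger breakpoint shifts that repeats induce while keeping a tight
#' window in unique sequence. Each read contributes at most once to a
#' cluster's support count.
#'
#' @param signals Signal table from [extract_signals()].
#' @param base_window Minimum clustering window in bp.
#' @param repeat_tolerance_factor Unitless multiplier on the running median
#'   signal size.
#' @return A `data.frame` of clusters with `start`/`end` (median breakpoint
#'   and median span), `size_estimate`, `n_support` (distinct reads),
#'   `mean_mapq`, and a `reads` list column.
#' @export
cluster_signals <- function(signals, base_window = 500L,
                            repeat_tolerance_factor = 2) {
  if (nrow(signals) == 0) return(empty_clusters())
  groups <- split(signals, list(signals$kind, signals$contig_id), drop = TRUE)
  res <- lapply(groups, function(g) {
    g <- g[order(g$pos, g$size), , drop = FALSE]
    n <- nrow(g)
    cl <- integer(n)
    cur <- 1L
    cl[1] <- cur
    members <- 1L
    for (i in seq_len(n)[-1]) {
      win <- max(base_window,
                 repeat_tolerance_factor * stats::median(g$size[members]))
      if (g$pos[i] - g$pos[members[length(members)]] <= win) {
        cl[i] <- cur
        members <- c(members, i)
      } else {
        cur <- cur + 1L
        cl[i] <- cur
        members <- i
      }
    }
    summarise_clusters(g, cl)
  })
  out <- do.call(rbind, c(res, list(empty_clusters())))
  rownames(out) <- NULL
  out[order(out$contig_id, out$start), , drop = FALSE]
}

summarise_clusters <- function(g, cl) {
  parts <- split(seq_len(nrow(g)), cl)
  rows <- lapply(parts, function(idx) {
    m <- g[idx, , drop = FALSE]
    start <- as.integer(round(stats::median(m$pos)))
    size <- as.integer(round(stats::median(m$size)))
    data.frame(kind = m$kind[1], contig_id = m$contig_id[1], start = start,
               end = start + size, size_estimate = size,
               size_exp = if (m$kind[1] == "expansion") size else NA_integer_,
               size_col = if (m$kind[1] == "collapse") size else NA_integer_,
               n_support = length(unique(m$read_id)), n_signals = nrow(m),
               mean_mapq = mean(m$mapq),
               reads = I(list(unique(m$read_id))),
               reads_exp = I(list(if (m$kind[1] == "expansion") unique(m$read_id) else character())),
               reads_col = I(list(if (m$kind[1] == "collapse") unique(m$read_id) else character())),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Merge overlapping expansion and collapse clusters into haplotype switches
#'
#' At a heterozygous SV breakpoint that the assembler resolved into a sequence
#' matching neither haplotype, reads from one haplotype signal a collapse and
#' reads from the other an expansion at the same locus. An expansion cluster
#' whose interval (padded by `base_window`) intersects a collapse cluster is
#' merged into one haplotype-switch candidate; when several collapses overlap
#' one expansion the nearest by midpoint wins, greedily by position, and each
#' cluster is consumed at most once. The switch's supporting reads are the
#' union of both sides.
#'
#' @param expansions,collapses Cluster tables from [cluster_signals()].
#' @param base_window Padding in bp for the overlap test.
#' @return A list with `switches`, `expansions` (unconsumed), `collapses`
#'   (unconsumed).
#' @export
merge_haplotype_switches <- function(expansions, collapses, base_window = 500L) {
  if (nrow(expansions) == 0 || nrow(collapses) == 0)
    return(list(switches = empty_clusters(), expansions = expansions,
                collapses = collapses))
  used_col <- rep(FALSE, nrow(collapses))
  used_exp <- rep(FALSE, nrow(expansions))
  ## all compatible pairs, assigned one-to-one from the nearest midpoint up
  pairs <- list()
  for (i in seq_len(nrow(expansions))) {
    e <- expansions[i, ]
    cand <- which(collapses$contig_id == e$contig_id &
                    collapses$start <= e$end + base_window &
                    collapses$end >= e$start - base_window)
    mid_e <- (e$start + e$end) / 2
    for (j in cand) {
      mid_c <- (collapses$start[j] + collapses$end[j]) / 2
      pairs[[length(pairs) + 1]] <- c(i, j, abs(mid_c - mid_e))
    }
  }
  switches <- list()
  if (length(pairs) > 0) pairs <- pairs[order(vapply(pairs, `[`, 0, 3))]
  for (pr in pairs) {
    i <- pr[1]; j <- pr[2]
    if (used_exp[i] || used_col[j]) next
    e <- expansions[i, ]
    co <- collapses[j, ]
    used_col[j] <- TRUE
    used_exp[i] <- TRUE
    reads <- unique(c(e$reads[[1]], co$reads[[1]]))
    n_sig <- e$n_signals + co$n_signals
    switches[[length(switches) + 1]] <- data.frame(
      kind = "haplotype_switch", contig_id = e$contig_id,
      start = min(e$start, co$start), end = max(e$end, co$end),
      size_estimate = max(e$size_estimate, co$size_estimate),
      size_exp = e$size_estimate, size_col = co$size_estimate,
      n_support = length(reads), n_signals = n_sig,
      mean_mapq = (e$mean_mapq * e$n_signals + co$mean_mapq * co$n_signals) / n_sig,
      reads = I(list(reads)), reads_exp = I(list(e$reads[[1]])),
      reads_col = I(list(co$reads[[1]])), stringsAsFactors = FALSE)
  }
  list(switches = do.call(rbind, c(switches, list(empty_clusters()))),
       expansions = expansions[!used_exp, , drop = FALSE],
       collapses = collapses[!used_col, , drop = FALSE])
}

#' Filter cluster candidates into structural error calls
#'
#' Separates assembly errors from genetic variants: a true error disagrees
#' with every read (support ratio near 100%), a heterozygous variant with only
#' the reads of one haplotype (near 50%), and a homozygous variant with none.
#' A candidate is kept iff its distinct-read support is at least
#' `min_support`, its support ratio (supporting reads / mean local coverage
#' over the padded interval) is at least `ratio_cutoff`, its local coverage
#' does not exceed `depth_cap` times the assembly mean depth (excessive
#' coverage marks collapsed repeats with unreliable alignments), and its mean
#' mapping quality is at least `mq_cutoff`.
#'
#' @param clusters Cluster candidates ([cluster_signals()] output, possibly
#'   including haplotype-switch rows from [merge_haplotype_switches()]).
#' @param depth_profiles Named list of per-contig coverage vectors
#'   ([depth_profile()]).
#' @param mean_depth Assembly-wide mean alignment depth.
#' @param min_support Minimum distinct supporting reads.
#' @param ratio_cutoff Minimum support ratio.
#' @param depth_cap Local-coverage cap as a multiple of `mean_depth`.
#' @param mq_cutoff Minimum mean mapping quality of supporting segments.
#' @param pad Padding in bp around the candidate interval for local coverage.
#' @return A `data.frame` of class `structural_errors`, sorted by contig and
#'   start, with capitalised `kind` labels (`Expansion`, `Collapse`,
#'   `HaplotypeSwitch`, `Inversion`).
#' @export
filter_structural <- function(clusters, depth_profiles, mean_depth,
                              min_support = 3L, ratio_cutoff = 0.7,
                              depth_cap = 3, mq_cutoff = 20, pad = 50L) {
  if (nrow(clusters) == 0) {
    out <- cbind(empty_clusters(),
                 data.frame(local_depth = numeric(), support_ratio = numeric()))
    class(out) <- c("structural_errors", "data.frame")
    return(out)
  }
  local_depth <- vapply(seq_len(nrow(clusters)), function(i) {
    d <- depth_profiles[[clusters$contig_id[i]]]
    if (is.null(d)) return(NA_real_)
    lo <- max(1L, clusters$start[i] + 1L - pad)
    hi <- min(length(d), clusters$end[i] + pad)
    if (hi < lo) return(NA_real_)
    mean(d[lo:hi])
  }, numeric(1))
  ratio <- clusters$n_support / pmax(local_depth, 1e-9)
  keep <- clusters$n_support >= min_support &
    ratio >= ratio_cutoff &
    local_depth <= depth_cap * mean_depth &
    clusters$mean_mapq >= mq_cutoff
  keep[is.na(keep)] <- FALSE
  out <- clusters[keep, , drop = FALSE]
  out$local_depth <- local_depth[keep]
  out$support_ratio <- ratio[keep]
  label <- c(expansion = "Expansion", collapse = "Collapse",
             haplotype_switch = "HaplotypeSwitch", inversion = "Inversion")
  out$kind <- unname(label[out$kind])
  out <- out[order(out$contig_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("structural_errors", "data.frame")
  out
}

#' Detect structural assembly errors from alignment segments
#'
#' Driver tying together [extract_signals()], [cluster_signals()],
#' [merge_haplotype_switches()], and [filter_structural()].
#'
#' @param segments Segment table from [parse_alignments()].
#' @param contigs Assembly as a [Biostrings::DNAStringSet].
#' @param params Parameter list from [eval_params()].
#' @param depth_profiles Optional precomputed named list of per-contig depth
#'   vectors; computed from `segments` when missing.
#' @return A `structural_errors` data.frame (see [filter_structural()]).
#' @export
detect_structural_errors <- function(segments, contigs,
                                     params = eval_params("hifi"),
                                     depth_profiles = NULL) {
  if (is.null(depth_profiles)) {
    depth_profiles <- lapply(setNames(seq_names(contigs), seq_names(contigs)), function(cid) {
      depth_profile(segments[segments$contig_id == cid, , drop = FALSE],
                    Biostrings::width(contigs)[seq_names(contigs) == cid][1])
    })
  }
  total_bases <- sum(as.numeric(Biostrings::width(contigs)))
  seg <- segments[!segments$is_secondary, , drop = FALSE]
  mean_depth <- sum(as.numeric(seg$contig_end - seg$contig_start)) /
    max(total_bases, 1)
  sig <- extract_signals(seg, min_size = params$min_structural_size)
  cl <- cluster_signals(sig, base_window = params$base_window,
                        repeat_tolerance_factor = params$repeat_tolerance_factor)
  merged <- merge_haplotype_switches(
    cl[cl$kind == "expansion", , drop = FALSE],
    cl[cl$kind == "collapse", , drop = FALSE],
    base_window = params$base_window)
  cand <- rbind(merged$switches, merged$expansions, merged$collapses,
                cl[cl$kind == "inversion", , drop = FALSE])
  filter_structural(cand, depth_profiles, mean_depth,
                    min_support = params$min_support,
                    ratio_cutoff = params$ratio_cutoff,
                    depth_cap = params$depth_cap,
                    mq_cutoff = params$mq_cutoff)
}
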