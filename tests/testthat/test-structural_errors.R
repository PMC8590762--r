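test_that("CIGAR indel runs become expansion/collapse signals at >= 50 bp", {
  base <- seg_row("r1", "c1", 0L, 200L, 0L, 140L, cigar = "100M60D40M")
  sig <- extract_signals(base)
  expect_equal(sig$kind, "expansion")
  expect_equal(sig$pos, 100L)
  expect_equal(sig$size, 60L)

  ins <- seg_row("r1", "c1", 0L, 140L, 0L, 200L, cigar = "100M60I40M")
  sig2 <- extract_signals(ins)
  expect_equal(sig2$kind, "collapse")
  expect_equal(sig2$pos, 100L)
  expect_equal(sig2$size, 60L)

  small <- seg_row("r1", "c1", 0L, 150L, 0L, 140L, cigar = "100M10D40M")
  expect_equal(nrow(extract_signals(small)), 0L)
})

test_that("split same-strand alignments yield gap/overlap signals", {
  # contig gap 200, read gap 0 -> expansion of 200 at the junction
  exp2 <- rbind(
    seg_row("r1", "c1", 0L, 1000L, 0L, 1000L, cigar = "1000M1000S",
            read_len = 2000L),
    seg_row("r1", "c1", 1200L, 2200L, 1000L, 2000L, cigar = "1000S1000M",
            read_len = 2000L, is_supplementary = TRUE))
  sig <- extract_signals(exp2)
  expect_equal(sig$kind, "expansion")
  expect_equal(sig$pos, 1000L)
  expect_equal(sig$size, 200L)

  # read gap 300, contig gap 0 -> collapse of 300
  col2 <- rbind(
    seg_row("r2", "c1", 0L, 1000L, 0L, 1000L, cigar = "1000M1300S",
            read_len = 2300L),
    seg_row("r2", "c1", 1000L, 2000L, 1300L, 2300L, cigar = "1300S1000M",
            read_len = 2300L, is_supplementary = TRUE))
  sig2 <- extract_signals(col2)
  expect_equal(sig2$kind, "collapse")
  expect_equal(sig2$size, 300L)

  # same situation on the minus strand: contig order is reversed
  exp2m <- rbind(
    seg_row("r3", "c1", 1200L, 2200L, 0L, 1000L, strand = "-",
            cigar = "1000M1000H", read_len = 2000L),
    seg_row("r3", "c1", 0L, 1000L, 1000L, 2000L, strand = "-",
            cigar = "1000H1000M", read_len = 2000L, is_supplementary = TRUE))
  sig3 <- extract_signals(exp2m)
  expect_equal(sig3$kind, "expansion")
  expect_equal(sig3$pos, 1000L)
  expect_equal(sig3$size, 200L)
})

test_that("a strand-flipped middle segment yields an inversion signal", {
  segs <- rbind(
    seg_row("r1", "c1", 0L, 1000L, 0L, 1000L),
    seg_row("r1", "c1", 1000L, 2000L, 1000L, 2000L, strand = "-",
            is_supplementary = TRUE),
    seg_row("r1", "c1", 2000L, 3000L, 2000L, 3000L, is_supplementary = TRUE))
  sig <- extract_signals(segs)
  inv <- sig[sig$kind == "inversion", ]
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$pos, 1000L)
  expect_equal(inv$size, 1000L)

  # a two-segment flip is ambiguous and yields no inversion signal
  two <- segs[1:2, ]
  expect_equal(nrow(extract_signals(two)[
    extract_signals(two)$kind == "inversion", ]), 0L)
})

test_that("greedy clustering groups nearby signals and counts distinct reads", {
  sig <- data.frame(kind = "expansion", contig_id = "c1",
                    pos = c(98L, 100L, 104L), size = c(60L, 61L, 60L),
                    read_id = c("a", "b", "c"), mapq = 60L,
                    stringsAsFactors = FALSE)
  cl <- cluster_signals(sig, base_window = 500)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_support, 3L)
  expect_equal(cl$size_estimate, 60L)

  far <- sig; far$pos <- c(100L, 10000L, 10010L)
  expect_equal(nrow(cluster_signals(far, base_window = 500)), 2L)

  same_read <- sig[1:2, ]; same_read$read_id <- "a"
  cl2 <- cluster_signals(same_read, base_window = 500)
  expect_equal(cl2$n_support, 1L)
})

test_that("clustering is order-invariant and idempotent", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    sig <- data.frame(kind = "collapse", contig_id = "c1",
                      pos = sample(0:20000, n), size = sample(50:300, n, TRUE),
                      read_id = paste0("r", seq_len(n)), mapq = 60L,
                      stringsAsFactors = FALSE)
    a <- cluster_signals(sig)
    b <- cluster_signals(sig[sample(n), ])
    expect_equal(a$start, b$start)
    expect_equal(a$n_support, b$n_support)
    # representatives re-cluster to themselves
    rep_sig <- data.frame(kind = a$kind, contig_id = a$contig_id,
                          pos = a$start, size = a$size_estimate,
                          read_id = paste0("q", seq_len(nrow(a))), mapq = 60L,
                          stringsAsFactors = FALSE)
    expect_equal(cluster_signals(rep_sig)$start, a$start)
  }
})

mk_cluster <- function(kind, start, size, reads, contig = "c1", mapq = 60) {
  data.frame(kind = kind, contig_id = contig, start = start,
             end = start + size, size_estimate = size,
             size_exp = if (kind == "expansion") size else NA_integer_,
             size_col = if (kind == "collapse") size else NA_integer_,
             n_support = length(reads), n_signals = length(reads),
             mean_mapq = mapq, reads = I(list(reads)),
             reads_exp = I(list(if (kind == "expansion") reads else character())),
             reads_col = I(list(if (kind == "collapse") reads else character())),
             stringsAsFactors = FALSE)
}

test_that("overlapping expansion and collapse clusters merge into a switch", {
  e <- mk_cluster("expansion", 1000L, 60L, paste0("e", 1:12))
  co <- mk_cluster("collapse", 1010L, 60L, paste0("c", 1:13))
  m <- merge_haplotype_switches(e, co)
  expect_equal(nrow(m$switches), 1L)
  expect_equal(m$switches$n_support, 25L)
  expect_equal(nrow(m$expansions), 0L)
  expect_equal(nrow(m$collapses), 0L)

  far <- mk_cluster("collapse", 900000L, 60L, "x")
  m2 <- merge_haplotype_switches(e, far)
  expect_equal(nrow(m2$switches), 0L)
  expect_equal(nrow(m2$expansions), 1L)
  expect_equal(nrow(m2$collapses), 1L)
})

test_that("competing merges resolve to the nearest collapse by midpoint", {
  e1 <- mk_cluster("expansion", 1000L, 60L, paste0("a", 1:5))
  e2 <- mk_cluster("expansion", 1300L, 60L, paste0("b", 1:5))
  co <- mk_cluster("collapse", 1250L, 60L, paste0("c", 1:5))
  m <- merge_haplotype_switches(rbind(e1, e2), co)
  expect_equal(nrow(m$switches), 1L)
  # enumeration: |1330 - 1280| = 50 beats |1030 - 1280| = 250, so e2 merges
  expect_true("b1" %in% m$switches$reads[[1]])
  expect_equal(m$expansions$start, 1000L)
})

test_that("the support-ratio filter separates errors from variants", {
  depth <- list(c1 = rep(30L, 5000))
  # clear error: 28 of ~30 reads support
  clear <- mk_cluster("expansion", 1000L, 80L, paste0("r", 1:28))
  kept <- filter_structural(clear, depth, mean_depth = 30)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$kind, "Expansion")
  expect_gt(kept$support_ratio, 0.9)

  # below the three-read support floor
  weak <- mk_cluster("collapse", 1000L, 80L, paste0("r", 1:2))
  expect_equal(nrow(filter_structural(weak, depth, 30)), 0L)

  # heterozygous variant: ~50% support ratio
  het <- mk_cluster("collapse", 1000L, 80L, paste0("r", 1:15))
  expect_equal(nrow(filter_structural(het, depth, 30)), 0L)

  # excessive local coverage or poor mapping quality is filtered
  deep <- list(c1 = rep(300L, 5000))
  loud <- mk_cluster("expansion", 1000L, 80L, paste0("r", 1:290))
  expect_equal(nrow(filter_structural(loud, deep, mean_depth = 30)), 0L)
  lowmq <- mk_cluster("expansion", 1000L, 80L, paste0("r", 1:28), mapq = 5)
  expect_equal(nrow(filter_structural(lowmq, depth, 30)), 0L)
})

test_that("reported errors keep the size and support invariants", {
  depth <- list(c1 = rep(50L, 20000))
  cl <- rbind(mk_cluster("expansion", 1000L, 60L, paste0("r", 1:48)),
              mk_cluster("collapse", 5000L, 120L, paste0("s", 1:45)),
              mk_cluster("inversion", 9000L, 800L, paste0("t", 1:44)))
  out <- filter_structural(cl, depth, 50)
  expect_true(all(out$n_support >= 3))
  expect_true(all(out$size_estimate >= 50))
  expect_equal(out$kind, c("Expansion", "Collapse", "Inversion"))
  expect_true(all(diff(out$start) > 0))  # sorted by position
})
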