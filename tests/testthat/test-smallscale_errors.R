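## A tiny handcrafted contig with reads laid out by CIGAR for pileup tests.
pileup_fixture <- function(records, contig = strrep("A", 40)) {
  segs <- do.call(rbind, lapply(records, function(r) do.call(seg_row, r)))
  pileup(segs, contig)
}

test_that("pileup counts spanning reads, bases, insertions, and deletions", {
  contig <- paste0(strrep("A", 10), "G", strrep("A", 29))  # G at 0-based 10
  reads3 <- lapply(1:3, function(i)
    list(read_id = paste0("r", i), contig_id = "c1", contig_start = 0L,
         contig_end = 40L, read_start = 0L, read_end = 40L,
         cigar = "40M", seq = paste0(strrep("A", 10), "G", strrep("A", 29))))
  pu <- pileup_fixture(reads3, contig)
  expect_equal(pu$depth[11], 3L)
  expect_equal(unname(pu$bases["G", 11]), 3L)
  expect_equal(sum(pu$ins), 0L)
  expect_equal(sum(pu$del), 0L)

  # 2 reads carry C at the G position, 1 carries the contig base
  mixed <- c(
    lapply(1:2, function(i)
      list(read_id = paste0("c", i), contig_id = "c1", contig_start = 0L,
           contig_end = 40L, read_start = 0L, read_end = 40L, cigar = "40M",
           seq = paste0(strrep("A", 10), "C", strrep("A", 29)))),
    list(list(read_id = "g", contig_id = "c1", contig_start = 0L,
              contig_end = 40L, read_start = 0L, read_end = 40L, cigar = "40M",
              seq = paste0(strrep("A", 10), "G", strrep("A", 29)))))
  pu2 <- pileup_fixture(mixed, contig)
  expect_equal(unname(pu2$bases["C", 11]), 2L)
  expect_equal(unname(pu2$bases["G", 11]), 1L)

  # a 1-bp insertion after 0-based position 10 lands at anchor 10
  insr <- list(list(read_id = "i", contig_id = "c1", contig_start = 0L,
                    contig_end = 40L, read_start = 0L, read_end = 41L,
                    cigar = "11M1I29M", seq = strrep("A", 41)))
  pu3 <- pileup_fixture(insr, contig)
  expect_equal(pu3$ins[11], 1L)

  # a deletion counts at each deleted column and keeps the column spanned
  delr <- list(list(read_id = "d", contig_id = "c1", contig_start = 0L,
                    contig_end = 40L, read_start = 0L, read_end = 38L,
                    cigar = "10M2D28M", seq = strrep("A", 38)))
  pu4 <- pileup_fixture(delr, contig)
  expect_equal(pu4$del[11:12], c(1L, 1L))
  expect_equal(pu4$depth[11:12], c(1L, 1L))

  # structural-scale indels are excluded from the small tallies
  bigd <- list(list(read_id = "D", contig_id = "c1", contig_start = 0L,
                    contig_end = 70L, read_start = 0L, read_end = 10L,
                    cigar = "5M60D5M", seq = strrep("A", 10)))
  pu5 <- pileup_fixture(bigd, strrep("A", 80))
  expect_equal(sum(pu5$del), 0L)
  expect_equal(pu5$depth[20], 1L)
})

test_that("the 20% support pre-filter is inclusive at the boundary", {
  mk_pu <- function(n_alt, depth = 30L) {
    contig <- strrep("A", 21)
    recs <- lapply(seq_len(depth), function(i) {
      alt <- i <= n_alt
      list(read_id = paste0("r", i), contig_id = "c1", contig_start = 0L,
           contig_end = 21L, read_start = 0L, read_end = 21L, cigar = "21M",
           seq = paste0(strrep("A", 10), if (alt) "T" else "A", strrep("A", 10)))
    })
    pileup_fixture(recs, contig)
  }
  expect_equal(nrow(candidate_small_errors(mk_pu(5))), 0L)   # 0.167 < 0.20
  ret <- candidate_small_errors(mk_pu(6))                     # 0.200 kept
  expect_equal(nrow(ret), 1L)
  expect_equal(ret$pos, 10L)
  expect_equal(ret$n_supp, 6L)
  expect_equal(ret$alt_base, "T")
  expect_equal(nrow(candidate_small_errors(mk_pu(29))), 1L)
  # columns below the callable depth are skipped
  shallow <- mk_pu(3, depth = 4L)
  expect_equal(nrow(candidate_small_errors(shallow, min_depth = 5)), 0L)
})

test_that("binomial p-values are exact and match outcome enumeration", {
  expect_equal(binomial_pvalue(10, 10, 0.5), 0.5^10)
  expect_equal(binomial_pvalue(2, 4, 0.5), 11 / 16)
  expect_equal(binomial_pvalue(0, 25, 0.3), 1)
  expect_error(binomial_pvalue(5, 4, 0.5), "n_supp")
  expect_error(binomial_pvalue(1, 4, 1.2), "p")

  set.seed(51)
  for (i in 1:40) {
    n <- sample(1:12, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.05, 0.95)
    expect_lt(abs(binomial_pvalue(k, n, p) - binom_tail_brute(k, n, p)), 1e-12)
  }
})

test_that("p-values are monotone non-increasing in support", {
  for (p in c(0.4, 0.5)) {
    pv <- binomial_pvalue(0:40, 40, p)
    expect_true(all(diff(pv) <= 1e-15))
  }
})

test_that("calling applies chemistry-specific nulls and thresholds", {
  cand <- data.frame(pos = c(10L, 20L, 30L), event = c("sub", "sub", "sub"),
                     size = 1L, n_reads = 20L, n_supp = c(19L, 10L, 13L),
                     alt_base = "T", stringsAsFactors = FALSE)
  hifi <- call_small_errors(cand, "hifi")
  expect_equal(hifi$pos, 10L)  # 19/20 kept, 10/20 (het-like) rejected
  expect_equal(hifi$kind, "BaseSubstitution")
  expect_lt(hifi$p_value, 0.01)
  expect_equal(hifi$p_value, binomial_pvalue(19, 20, 0.5))

  clr <- call_small_errors(cand, "clr")
  expect_setequal(clr$pos, c(10L, 30L))  # 13/20 significant at p=0.4
  expect_equal(clr$p_value[clr$pos == 30L], binomial_pvalue(13, 20, 0.4),
               tolerance = 1e-12)

  ev <- data.frame(pos = 1:2, event = c("ins", "del"), size = 1L,
                   n_reads = 30L, n_supp = 29L, alt_base = NA_character_,
                   stringsAsFactors = FALSE)
  kinds <- call_small_errors(ev, "hifi")$kind
  expect_equal(kinds, c("SmallCollapse", "SmallExpansion"))
})

test_that("every reported error satisfies both filters", {
  set.seed(52)
  depth <- 40L
  contig <- random_dna_chr(60)
  recs <- lapply(seq_len(depth), function(i) {
    s <- contig
    if (i <= 38) substring(s, 31, 31) <- "A"  # near-unanimous alternative
    if (i <= 10) substring(s, 11, 11) <- "C"  # 25% support, het-unlike but weak
    list(read_id = paste0("r", i), contig_id = "c1", contig_start = 0L,
         contig_end = 60L, read_start = 0L, read_end = 60L, cigar = "60M",
         seq = s)
  })
  segs <- do.call(rbind, lapply(recs, function(r) do.call(seg_row, r)))
  calls <- detect_small_errors(segs, contig, "hifi")
  expect_true(all(calls$support_fraction >= 0.2))
  expect_true(all(calls$p_value < 0.01))
  if (substring(contig, 31, 31) != "A") {
    expect_true(30L %in% calls$pos)
    expect_equal(calls$read_allele[calls$pos == 30L], "A")
    expect_equal(calls$contig_allele[calls$pos == 30L],
                 substring(contig, 31, 31))
  }
  expect_false(10L %in% calls$pos)  # 10/40 fails the binomial test
})

test_that("insertion alleles come from the majority inserted sequence", {
  contig <- strrep("A", 30)
  recs <- lapply(1:12, function(i)
    list(read_id = paste0("r", i), contig_id = "c1", contig_start = 0L,
         contig_end = 30L, read_start = 0L, read_end = 31L,
         cigar = "15M1I15M",
         seq = paste0(strrep("A", 15), if (i <= 10) "G" else "C",
                      strrep("A", 15))))
  segs <- do.call(rbind, lapply(recs, function(r) do.call(seg_row, r)))
  calls <- detect_small_errors(segs, contig, "hifi")
  expect_equal(calls$kind, "SmallCollapse")
  expect_equal(calls$pos, 14L)
  expect_equal(calls$read_allele, "G")
})
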