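mk_block <- function(contig_id, cs, ce, strand, ref_id, rs, re, cigar) {
  data.frame(contig_id = contig_id, contig_start = cs, contig_end = ce,
             strand = strand, ref_id = ref_id, ref_start = rs, ref_end = re,
             mapq = 60L, cigar = cigar, stringsAsFactors = FALSE)
}

test_that("contigs map to the reference as expected blocks", {
  set.seed(71)
  ref <- Biostrings::DNAStringSet(c(chr = random_dna_chr(120000)))
  # contig identical to a reference slice: one full-length block
  ctg <- Biostrings::DNAStringSet(c(c1 = substring(as.character(ref), 10001, 60000)))
  blocks <- map_contigs(ctg, ref)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$ref_start, 10000L)
  expect_equal(blocks$ref_end, 60000L)

  # contig made of slices from two reference sequences: two blocks
  ref2 <- Biostrings::DNAStringSet(c(chrA = random_dna_chr(60000),
                                     chrB = random_dna_chr(60000)))
  ctg2 <- Biostrings::DNAStringSet(c(c2 = paste0(
    substring(as.character(ref2[["chrA"]]), 1, 30000),
    substring(as.character(ref2[["chrB"]]), 30001, 60000))))
  blocks2 <- map_contigs(ctg2, ref2)
  expect_equal(nrow(blocks2), 2L)
  expect_setequal(blocks2$ref_id, c("chrA", "chrB"))

  # an unalignable random contig yields zero blocks
  ctg3 <- Biostrings::DNAStringSet(c(c3 = random_dna_chr(30000)))
  expect_equal(nrow(map_contigs(ctg3, ref)), 0L)
})

test_that("reference statistics follow their definitions", {
  set.seed(72)
  ref <- Biostrings::DNAStringSet(c(chr = random_dna_chr(100000)))
  ctg <- Biostrings::DNAStringSet(c(c1 = substring(as.character(ref), 1, 80000)))
  blocks <- map_contigs(ctg, ref)
  rs <- ref_stats(blocks, ctg, ref)
  expect_equal(rs$na50, contig_stats(ctg)$n50)
  expect_equal(rs$contig_mapping_rate, 1.0)
  expect_equal(rs$genome_coverage, 0.8)

  # handcrafted blocks: 60 kb + 30 kb aligned of a 100-kb contig
  fake <- rbind(mk_block("c1", 0L, 60000L, "+", "chr", 0L, 60000L, "60000M"),
                mk_block("c1", 70000L, 100000L, "+", "chr", 60000L, 90000L,
                         "30000M"))
  big_ctg <- Biostrings::DNAStringSet(c(c1 = strrep("A", 100000)))
  rs2 <- ref_stats(fake, big_ctg, ref)
  expect_equal(rs2$contig_mapping_rate, 0.9)

  # overlapping ref blocks count once: [0,50) + [25,75) of 100 bp = 0.75
  small_ref <- Biostrings::DNAStringSet(c(chr = strrep("A", 100)))
  small_ctg <- Biostrings::DNAStringSet(c(c1 = strrep("A", 100)))
  ov <- rbind(mk_block("c1", 0L, 50L, "+", "chr", 0L, 50L, "50M"),
              mk_block("c1", 25L, 75L, "+", "chr", 25L, 75L, "50M"))
  expect_equal(ref_stats(ov, small_ctg, small_ref)$genome_coverage, 0.75)
})

test_that("coordinate projection handles strand, indels, and gaps", {
  blocks <- mk_block("c1", 0L, 1000L, "+", "chr", 10000L, 11000L, "1000M")
  err <- data.frame(contig_id = "c1", start = 500L, stringsAsFactors = FALSE)
  pr <- project_to_reference(err, blocks)
  expect_equal(pr$ref_pos, 10500L)
  expect_equal(pr$projection, "exact")

  minus <- mk_block("c1", 0L, 1000L, "-", "chr", 10000L, 11000L, "1000M")
  prm <- project_to_reference(err, minus)
  expect_equal(prm$ref_pos, 10000L + (999L - 500L))

  # an error in an unaligned gap is flagged unprojectable
  gap_err <- data.frame(contig_id = "c1", start = 5000L,
                        stringsAsFactors = FALSE)
  prg <- project_to_reference(gap_err, blocks)
  expect_equal(prg$projection, "unprojectable")
  expect_true(is.na(prg$ref_pos))

  # a contig-side insertion has no image: nearest left match, approximate
  indel <- mk_block("c1", 0L, 1100L, "+", "chr", 10000L, 11000L,
                    "500M100I500M")
  ins_err <- data.frame(contig_id = "c1", start = 550L,
                        stringsAsFactors = FALSE)
  pri <- project_to_reference(ins_err, indel)
  expect_equal(pri$projection, "approximate")
  expect_equal(pri$ref_pos, 10499L)
  # after the insertion, coordinates shift back into register
  post <- data.frame(contig_id = "c1", start = 700L, stringsAsFactors = FALSE)
  expect_equal(project_to_reference(post, indel)$ref_pos, 10600L)
})

test_that("projection round-trips through a minimap2 alignment", {
  set.seed(73)
  refseq <- random_dna_chr(50000)
  ref <- Biostrings::DNAStringSet(c(chr = refseq))
  # contig = a slice whose middle 5 kb is inverted
  slice <- substring(refseq, 5001, 45000)
  inv <- paste0(substring(slice, 1, 20000),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(substring(slice, 20001, 25000)))),
                substring(slice, 25001))
  ctg <- Biostrings::DNAStringSet(c(c1 = inv))
  blocks <- map_contigs(ctg, ref)
  expect_gte(nrow(blocks), 2L)
  # positions on the forward part project to ref_pos = contig_pos + 5000
  fwd <- data.frame(contig_id = "c1", start = c(1000L, 10000L, 30000L),
                    stringsAsFactors = FALSE)
  pf <- project_to_reference(fwd, blocks)
  expect_equal(pf$ref_pos, fwd$start + 5000L)
  # a position inside the inverted block maps through the minus strand
  mid <- data.frame(contig_id = "c1", start = 22500L, stringsAsFactors = FALSE)
  pm <- project_to_reference(mid, blocks)
  expect_equal(pm$projection, "exact")
  expect_equal(pm$ref_pos, 22500L + 5000L - 1L, tolerance = 2)
})

test_that("dotplot segments draw diagonals and anti-diagonals", {
  blocks <- rbind(mk_block("c1", 0L, 100L, "+", "chr", 0L, 100L, "100M"),
                  mk_block("c1", 100L, 200L, "-", "chr", 100L, 200L, "100M"))
  dp <- dotplot_data(blocks)
  expect_equal(dp$contig_start[1], 0L)
  expect_lt(dp$contig_end[2], dp$contig_start[2])  # anti-diagonal
  expect_equal(nrow(dotplot_data(blocks[0, ])), 0L)
})
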