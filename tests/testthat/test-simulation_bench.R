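tiny_cfg <- function(...) {
  sim_config(genome_length = 3e5, n_gaps = 1L, n_snp = 60L, n_sv = 24L,
             error_composition = c(expansion = 2L, collapse = 2L,
                                   haplotype_switch = 1L, inversion = 1L),
             n_small_errors = 40L, read_depth = 8, margin = 15000L,
             min_frag = 5000L, ...)
}

gap_bases_of <- function(s) {
  g <- gregexpr("N{10,}", s)[[1]]
  if (g[1] == -1) 0L else sum(attr(g, "match.length"))
}

test_that("seeded simulation is byte-identical across runs", {
  run <- function() {
    set.seed(77)
    sim <- simulate_diploid(tiny_cfg())
    spiked <- spike_errors(sim)
    reads <- simulate_reads(list(sim$hap1, sim$hap2), tiny_cfg(), "clr")
    list(h1 = sim$hap1, h2 = sim$hap2,
         asm = as.character(spiked$assembly),
         truth = spiked$truth_structural,
         fq = readLines(reads$path))
  }
  a <- run(); b <- run()
  expect_identical(a$h1, b$h1)
  expect_identical(a$h2, b$h2)
  expect_identical(a$asm, b$asm)
  expect_identical(a$truth, b$truth)
  expect_identical(a$fq, b$fq)
})

test_that("heterozygous/homozygous assignment follows the configured split", {
  set.seed(78)
  cfg <- sim_config(genome_length = 3e6, n_snp = 100L, n_sv = 30L,
                    margin = 20000L)
  sim <- simulate_diploid(cfg)
  snp <- sim$variants[sim$variants$type == "snp", ]
  expect_equal(sum(snp$zygosity == "het"), 67L)
  expect_equal(sum(snp$zygosity == "hom"), 33L)
  expect_true(all(snp$hap[snp$zygosity == "hom"] == 0L))

  # no variants: haplotypes equal the base genome
  set.seed(79)
  cfg0 <- sim_config(genome_length = 1e5, n_snp = 0L, n_sv = 0L,
                     margin = 1000L, n_gaps = 0L)
  sim0 <- simulate_diploid(cfg0)
  expect_identical(sim0$hap1, sim0$genome)
  expect_identical(sim0$hap2, sim0$genome)
})

test_that("spiked truth counts and length accounting are exact", {
  set.seed(80)
  cfg <- tiny_cfg()
  sim <- simulate_diploid(cfg)
  spiked <- spike_errors(sim)
  expect_equal(nrow(spiked$truth_structural), 6L)
  expect_equal(as.vector(table(spiked$truth_structural$kind)[
    c("Collapse", "Expansion", "HaplotypeSwitch", "Inversion")]),
    c(2L, 2L, 1L, 1L))
  expect_equal(nrow(spiked$truth_small), 40L)

  # length accounting: assembly = hap1 + expansions - collapses +- small
  tr <- spiked$truth_structural
  delta <- sum(tr$size[tr$kind == "Expansion"]) -
    sum(tr$size[tr$kind == "Collapse"])
  sw <- sim$variants[sim$variants$type == "ins" & sim$variants$hap == 1L, ]
  sm <- spiked$truth_small
  delta <- delta + sum(sm$kind == "SmallExpansion") -
    sum(sm$kind == "SmallCollapse")
  # haplotype switch removes the second half of its insertion SV
  switch_removed <- tr$size_col[tr$kind == "HaplotypeSwitch"]
  asm_len <- sum(Biostrings::width(spiked$assembly))
  gaps <- gregexpr("N{10,}", sim$hap1)[[1]]
  gap_bases <- sum(attr(gaps, "match.length"))
  expect_equal(asm_len, nchar(sim$hap1) - gap_bases + delta - switch_removed)

  # no errors requested: assembly equals haplotype 1 (minus N gaps)
  set.seed(81)
  cfg0 <- tiny_cfg()
  sim0 <- simulate_diploid(cfg0)
  spiked0 <- spike_errors(sim0, composition = c(expansion = 0L, collapse = 0L,
                                                haplotype_switch = 0L,
                                                inversion = 0L), n_small = 0L)
  expect_equal(sum(Biostrings::width(spiked0$assembly)),
               nchar(sim0$hap1) - gap_bases_of(sim0$hap1))
  expect_identical(paste(as.character(spiked0$assembly), collapse = ""),
                   gsub("N", "", sim0$hap1, fixed = TRUE))
})

test_that("truth coordinates point at the spiked loci on the assembly", {
  set.seed(82)
  cfg <- tiny_cfg()
  sim <- simulate_diploid(cfg)
  spiked <- spike_errors(sim)
  asm <- spiked$assembly
  tr <- spiked$truth_structural
  # an expansion's truth interval holds inserted sequence absent from hap1
  e <- tr[tr$kind == "Expansion", ][1, ]
  insseq <- substring(as.character(asm[[e$contig_id]]), e$start + 1L, e$end)
  expect_equal(nchar(insseq), e$size)
  expect_false(grepl(insseq, sim$hap1, fixed = TRUE))
})

test_that("read simulation meets its depth, length, and purity contracts", {
  set.seed(83)
  cfg <- sim_config(genome_length = 1e5, n_gaps = 0L, n_snp = 0L, n_sv = 0L,
                    read_depth = 10, read_length_mean = 5000,
                    read_length_sd = 1000, margin = 1000L,
                    read_accuracy = c(clr = 1.0, hifi = 1.0, nano = 1.0))
  sim <- simulate_diploid(cfg)
  reads <- simulate_reads(list(sim$hap1), cfg, "hifi")
  expect_lt(abs(reads$total_bases - 10 * 1e5) / (10 * 1e5), 0.02)
  # accuracy 1.0: every read is an exact substring (possibly revcomp)
  fq <- readLines(reads$path)
  ids <- sub("^@", "", fq[seq(1, length(fq), by = 4)])
  seqs <- fq[seq(2, length(fq), by = 4)]
  for (i in seq_len(min(20, length(seqs)))) {
    parts <- strsplit(ids[i], "_")[[1]]
    start <- as.integer(parts[3])
    fwdseq <- if (parts[4] == "f") seqs[i] else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs[i])))
    expect_identical(fwdseq,
                     substring(sim$hap1, start + 1L, start + nchar(seqs[i])))
  }
})

test_that("benchmark scoring implements greedy one-to-one matching", {
  truth <- data.frame(contig_id = "c1", start = c(1000L, 5000L, 9000L, 13000L),
                      kind = "Expansion", size = 100L,
                      stringsAsFactors = FALSE)
  calls <- data.frame(contig_id = "c1",
                      start = c(1020L, 5010L, 8990L, 13050L, 40000L),
                      kind = "Expansion", size = c(90L, 100L, 110L, 95L, 80L),
                      stringsAsFactors = FALSE)
  sc <- score_calls(calls, truth, "structural")
  expect_equal(sc$tp, 4L)
  expect_equal(sc$recall, 1.0)
  expect_equal(sc$precision, 0.8)
  expect_equal(sc$f1, 2 * 1 * 0.8 / 1.8)

  # identity case
  sc2 <- score_calls(truth, truth, "structural")
  expect_equal(sc2$f1, 1.0)

  # size tolerance: reciprocal overlap of sizes below 0.5 rejects the pair
  off <- calls[1, ]; off$size <- 900L
  expect_equal(score_calls(off, truth, "structural")$tp, 0L)

  # a haplotype switch matches expansion or collapse at its locus
  sw <- data.frame(contig_id = "c1", start = 1010L, kind = "HaplotypeSwitch",
                   size = 60L, stringsAsFactors = FALSE)
  expect_equal(score_calls(sw, truth[1, ], "structural")$tp, 1L)

  # no calls: precision undefined, F1 zero
  sc0 <- score_calls(calls[0, ], truth, "structural")
  expect_true(is.nan(sc0$precision))
  expect_equal(sc0$f1, 0)

  # one call cannot consume two truth records
  dup <- rbind(calls[1, ], calls[1, ])
  scd <- score_calls(dup, truth[1, ], "structural")
  expect_equal(scd$tp, 1L)
  expect_equal(scd$fp, 1L)
})

test_that("small-scale scoring matches kind within a small window", {
  truth <- data.frame(contig_id = "c1", pos = c(100L, 200L),
                      kind = c("BaseSubstitution", "SmallExpansion"),
                      size = 1L, stringsAsFactors = FALSE)
  calls <- data.frame(contig_id = "c1", pos = c(103L, 200L),
                      kind = c("BaseSubstitution", "SmallCollapse"),
                      size = 1L, stringsAsFactors = FALSE)
  sc <- score_calls(calls, truth, "small")
  expect_equal(sc$tp, 1L)  # kind mismatch at 200 is not a match
  expect_equal(score_calls(calls[1, ], truth, "small",
                           small_window = 2)$tp, 0L)
})

test_that("edit application and coordinate shifting agree", {
  set.seed(84)
  for (i in 1:15) {
    src <- random_dna_chr(2000)
    pos <- sort(sample(seq(50, 1900, by = 60), 8))
    edits <- data.frame(pos0 = pos,
                        ref_len = sample(c(0L, 1L, 5L), 8, replace = TRUE),
                        alt = replicate(8, paste(sample(c("", "T", "GGC"), 1),
                                                 collapse = "")),
                        stringsAsFactors = FALSE)
    out <- asmeval:::apply_edits(src, edits)
    probes <- setdiff(seq(10, 1990, by = 37),
                      unlist(lapply(seq_len(8), function(j)
                        edits$pos0[j]:(edits$pos0[j] + edits$ref_len[j]))))
    shifted <- asmeval:::shift_positions(probes, edits)
    expect_identical(substring(out, shifted + 1L, shifted + 1L),
                     substring(src, probes + 1L, probes + 1L))
  }
})
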