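## Shared fixtures and independent oracles. All fixtures are built in code.

## Write a minimal SAM file for handcrafted alignment records.
## records: list of c(qname, flag, rname, pos1, mapq, cigar, seq)
make_sam <- function(contigs, records, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)))
  body <- vapply(records, function(r) {
    paste(r[["qname"]], r[["flag"]], r[["rname"]], r[["pos"]], r[["mapq"]],
          r[["cigar"]], "*", 0, 0, r[["seq"]], "*", sep = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}

sam_rec <- function(qname, flag, rname, pos, mapq, cigar, seq = "*") {
  list(qname = qname, flag = flag, rname = rname, pos = pos, mapq = mapq,
       cigar = cigar, seq = seq)
}

## A segment-table row built directly (bypasses file IO).
seg_row <- function(read_id, contig_id, contig_start, contig_end, read_start,
                    read_end, strand = "+", mapq = 60L, cigar = NA_character_,
                    seq = NA_character_, read_len = read_end,
                    is_supplementary = FALSE, is_secondary = FALSE) {
  data.frame(read_id = read_id, contig_id = contig_id,
             contig_start = contig_start, contig_end = contig_end,
             read_start = read_start, read_end = read_end,
             read_len = read_len, strand = strand, mapq = mapq,
             is_supplementary = is_supplementary, is_secondary = is_secondary,
             is_primary = !is_supplementary && !is_secondary,
             cigar = cigar, seq = seq, stringsAsFactors = FALSE)
}

## Independent N50 oracle: enumerate suffixes of the descending-sorted lengths.
n50_brute <- function(lengths, total = sum(lengths)) {
  if (length(lengths) == 0 || total <= 0) return(0L)
  l <- sort(lengths, decreasing = TRUE)
  run <- 0
  for (i in seq_along(l)) {
    run <- run + l[i]
    if (run >= total / 2) return(as.integer(l[i]))
  }
  0L
}

## Independent depth oracle: literal per-position counting.
depth_brute <- function(L, starts0, ends0) {
  d <- integer(L)
  for (i in seq_along(starts0)) {
    for (p in seq_len(L) - 1L) {
      if (p >= starts0[i] && p < ends0[i]) d[p + 1L] <- d[p + 1L] + 1L
    }
  }
  d
}

## Independent binomial upper-tail oracle: enumerate all 2^n outcomes.
binom_tail_brute <- function(k, n, p) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  outcomes <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  sum(probs[rowSums(outcomes) >= k])
}

## Random error injection used by consensus tests (R-level, independent of the
## package's C++ read simulator).
mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (b in ch) {
    u <- runif(1)
    if (u < rate / 3) {
      out <- c(out, sample(setdiff(c("A", "C", "G", "T"), b), 1))
    } else if (u < 2 * rate / 3) {
      out <- c(out, b, sample(c("A", "C", "G", "T"), 1))
    } else if (u < rate) {
      # deletion
    } else out <- c(out, b)
  }
  paste(out, collapse = "")
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
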