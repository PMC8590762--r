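## Optional reference-based mode: contig-to-reference synteny statistics and
## projection of error coordinates onto the reference.

#' Align contigs to a reference genome
#'
#' Runs minimap2 with the assembly-to-reference preset (`asm5`) and `-c` so
#' base-level CIGARs are emitted, returning aligned blocks parsed from the
#' PAF output. Primary and supplementary alignments are kept.
#'
#' @param contigs Assembly FASTA path or [Biostrings::DNAStringSet].
#' @param reference Reference FASTA path or [Biostrings::DNAStringSet].
#' @param preset minimap2 preset (asm5 for closely related genomes).
#' @param threads Alignment threads.
#' @param minimap2 Path to the minimap2 executable.
#' @return A `data.frame` of blocks: `contig_id`, `contig_start`,
#'   `contig_end`, `strand`, `ref_id`, `ref_start`, `ref_end`, `mapq`,
#'   `cigar` (0-based half-open, contig coordinates on the original strand).
#' @export
map_contigs <- function(contigs, reference, preset = "asm5", threads = 1L,
                        minimap2 = Sys.which("minimap2")) {
  if (!nzchar(minimap2))
    stop("minimap2 not found on PATH", call. = FALSE)
  path_of <- function(x, what) {
    if (inherits(x, "DNAStringSet")) {
      p <- tempfile(fileext = paste0("_", what, ".fa")); write_fasta(x, p); p
    } else stop_if_missing_file(x)
  }
  ctg <- path_of(contigs, "ctg"); ref <- path_of(reference, "ref")
  paf <- tempfile(fileext = ".paf")
  log <- tempfile(fileext = ".log")
  status <- system2(minimap2, c("-c", "-x", preset, "--secondary=no",
                                "-t", threads, shQuote(ref), shQuote(ctg)),
                    stdout = paf, stderr = log)
  if (status != 0)
    stop("minimap2 exited with status ", status, ":\n",
         paste(readLines(log, warn = FALSE), collapse = "\n"), call. = FALSE)
  seg <- parse_paf_segments(paf)
  data.frame(contig_id = seg$read_id, contig_start = seg$read_start,
             contig_end = seg$read_end, strand = seg$strand,
             ref_id = seg$contig_id, ref_start = seg$contig_start,
             ref_end = seg$contig_end, mapq = seg$mapq, cigar = seg$cigar,
             stringsAsFactors = FALSE)
}

#' Reference-based synteny statistics
#'
#' NA50 is the N50 computed over aligned block lengths instead of contig
#' lengths, with the half-total taken over the full assembly length (so
#' unaligned sequence counts against it). Contig mapping rate is the aligned
#' fraction of contig bases (per-contig interval union); genome coverage is
#' the fraction of reference bases covered by at least one block.
#'
#' @param blocks Block table from [map_contigs()].
#' @param contigs Assembly [Biostrings::DNAStringSet] (or FASTA path).
#' @param reference Reference [Biostrings::DNAStringSet] (or FASTA path).
#' @return An object of class `ref_align_stats`.
#' @export
ref_stats <- function(blocks, contigs, reference) {
  if (!inherits(contigs, "DNAStringSet")) contigs <- read_fasta(contigs)
  if (!inherits(reference, "DNAStringSet")) reference <- read_fasta(reference)
  total_asm <- sum(as.numeric(Biostrings::width(contigs)))
  total_ref <- sum(as.numeric(Biostrings::width(reference)))
  blk_len <- blocks$contig_end - blocks$contig_start
  na50 <- weighted_nxx(blk_len, total = total_asm)
  aligned <- sum(vapply(split(blocks, blocks$contig_id), function(b)
    union_length(b$contig_start, b$contig_end), numeric(1)))
  covered <- sum(vapply(split(blocks, blocks$ref_id), function(b)
    union_length(b$ref_start, b$ref_end), numeric(1)))
  structure(list(
    na50 = na50,
    contig_mapping_rate = if (total_asm > 0) aligned / total_asm else 0,
    genome_coverage = if (total_ref > 0) covered / total_ref else 0,
    n_blocks = nrow(blocks)
  ), class = "ref_align_stats")
}

#' @export
print.ref_align_stats <- function(x, ...) {
  cat("Reference-based synteny\n")
  cat(sprintf("  NA50:            %d\n", x$na50))
  cat(sprintf("  mapping rate:    %.4f\n", x$contig_mapping_rate))
  cat(sprintf("  genome coverage: %.4f\n", x$genome_coverage))
  invisible(x)
}

#' Project contig coordinates onto the reference
#'
#' Maps each error's contig position through the CIGAR of the aligned block
#' containing it. Only match columns (M/=/X) have an image; positions inside
#' read-side insertions inherit the nearest match to their left and are
#' flagged approximate. Errors in unaligned contig regions are flagged
#' unprojectable and keep `NA` coordinates.
#'
#' @param errors A data.frame with `contig_id` and `start` (0-based) columns
#'   (structural or small-scale error tables both work; for small-scale pass
#'   a `pos` column as `start`).
#' @param blocks Block table from [map_contigs()].
#' @return `errors` with added `ref_id`, `ref_pos`, `projection`
#'   (`"exact"`, `"approximate"`, `"unprojectable"`).
#' @export
project_to_reference <- function(errors, blocks) {
  if (is.null(errors$start) && !is.null(errors$pos)) errors$start <- errors$pos
  n <- nrow(errors)
  errors$ref_id <- NA_character_
  errors$ref_pos <- NA_integer_
  errors$projection <- rep("unprojectable", n)
  for (i in seq_len(n)) {
    b <- blocks[blocks$contig_id == errors$contig_id[i] &
                  blocks$contig_start <= errors$start[i] &
                  blocks$contig_end > errors$start[i], , drop = FALSE]
    if (nrow(b) == 0) next
    b <- b[which.max(b$contig_end - b$contig_start), , drop = FALSE]
    pr <- project_pos(errors$start[i], b)
    if (!is.na(pr$ref_pos)) {
      errors$ref_id[i] <- b$ref_id
      errors$ref_pos[i] <- pr$ref_pos
      errors$projection[i] <- pr$kind
    }
  }
  errors
}

## Walk one block's CIGAR to map a contig position to a reference position.
## PAF convention: the CIGAR follows the reference ascending; for '-' strand
## blocks the contig is consumed from contig_end downward.
project_pos <- function(pos, b) {
  ops <- regmatches(b$cigar, gregexpr("[0-9]+[MIDNSHP=X]", b$cigar))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  r <- b$ref_start
  fwd <- b$strand == "+"
  c0 <- if (fwd) b$contig_start else b$contig_end  # exclusive top for '-'
  last_match_ref <- NA_integer_
  for (j in seq_along(op)) {
    l <- len[j]
    if (op[j] %in% c("M", "=", "X")) {
      if (fwd) {
        if (pos < c0 + l && pos >= c0) return(list(ref_pos = r + (pos - c0), kind = "exact"))
        c0 <- c0 + l
      } else {
        if (pos >= c0 - l && pos < c0) return(list(ref_pos = r + (c0 - 1L - pos), kind = "exact"))
        c0 <- c0 - l
      }
      r <- r + l
      last_match_ref <- r - 1L
    } else if (op[j] == "I") {        # contig-only sequence
      hit <- if (fwd) (pos >= c0 && pos < c0 + l) else (pos >= c0 - l && pos < c0)
      if (hit) return(list(ref_pos = last_match_ref, kind = "approximate"))
      c0 <- if (fwd) c0 + l else c0 - l
    } else if (op[j] %in% c("D", "N")) {
      r <- r + l
    }
  }
  list(ref_pos = NA_integer_, kind = "unprojectable")
}

#' Dotplot segment table
#'
#' Plotting-ready table of aligned segment pairs, sorted by reference
#' coordinate: a full-identity assembly gives a single diagonal, an inverted
#' segment an anti-diagonal (its contig coordinates decrease).
#'
#' @param blocks Block table from [map_contigs()].
#' @return A `data.frame` with `ref_id`, `ref_start`, `ref_end`, `contig_id`,
#'   `contig_start`, `contig_end`, `strand`; on `-` rows `contig_start` >
#'   `contig_end` so segments draw with the correct slope.
#' @export
dotplot_data <- function(blocks) {
  if (nrow(blocks) == 0) {
    return(data.frame(ref_id = character(), ref_start = integer(),
                      ref_end = integer(), contig_id = character(),
                      contig_start = integer(), contig_end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    ref_id = blocks$ref_id, ref_start = blocks$ref_start,
    ref_end = blocks$ref_end, contig_id = blocks$contig_id,
    contig_start = ifelse(blocks$strand == "+", blocks$contig_start,
                          blocks$contig_end),
    contig_end = ifelse(blocks$strand == "+", blocks$contig_end,
                        blocks$contig_start),
    strand = blocks$strand, stringsAsFactors = FALSE)
  out[order(out$ref_id, out$ref_start), , drop = FALSE]
}
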