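#' Align long reads to contigs with minimap2
#'
#' Invokes the external `minimap2` executable with the long-read preset
#' matching the sequencing chemistry and converts its SAM output to a
#' coordinate-sorted, indexed BAM via [Rsamtools::asBam()]. Secondary
#' alignments are suppressed (`--secondary=no`); supplementary alignments are
#' kept since split reads carry the structural-error signals.
#'
#' @param reads Path to a FASTA/FASTQ file of reads (gzip ok).
#' @param contigs Path to the assembly FASTA, or a [Biostrings::DNAStringSet].
#' @param datatype One of `"hifi"`, `"clr"`, `"nano"`; selects the minimap2
#'   preset (`map-hifi`, `map-pb`, `map-ont`).
#' @param out Output BAM path (without or with `.bam` extension).
#' @param threads Number of alignment threads.
#' @param minimap2 Path to the minimap2 executable.
#' @param extra_args Additional command-line arguments (character vector);
#'   makes the invocation a pluggable contract so presets can be overridden or
#'   precomputed alignments supplied instead via [parse_alignments()].
#' @param sort Convert to coordinate-sorted, indexed BAM (default). With
#'   `sort = FALSE` the raw SAM is returned, which is faster when the
#'   alignment is only an intermediate for error calling.
#' @return Path to the sorted BAM (or SAM) file.
#' @export
align_reads <- function(reads, contigs, datatype = c("hifi", "clr", "nano"),
                        out = tempfile(fileext = if (sort) ".bam" else ".sam"),
                        threads = 1L, minimap2 = Sys.which("minimap2"),
                        extra_args = character(), sort = TRUE) {
  datatype <- match.arg(datatype)
  if (!nzchar(minimap2))
    stop("minimap2 not found on PATH; install it (e.g. via conda: ",
         "'conda install -c bioconda minimap2') or pass precomputed ",
         "alignments to parse_alignments()", call. = FALSE)
  stop_if_missing_file(reads)
  if (inherits(contigs, "DNAStringSet")) {
    ctg_path <- tempfile(fileext = ".fa")
    write_fasta(contigs, ctg_path)
  } else {
    ctg_path <- stop_if_missing_file(contigs)
  }
  preset <- c(hifi = "map-hifi", clr = "map-pb", nano = "map-ont")[[datatype]]
  sam <- if (sort) tempfile(fileext = ".sam") else out
  if (sort) on.exit(unlink(sam), add = TRUE)
  log <- tempfile(fileext = ".log")
  status <- system2(minimap2,
                    c("-a", "-x", preset, "--secondary=no", "-t", threads,
                      extra_args, shQuote(ctg_path), shQuote(reads)),
                    stdout = sam, stderr = log)
  if (status != 0)
    stop("minimap2 exited with status ", status, ":\n",
         paste(readLines(log, warn = FALSE), collapse = "\n"), call. = FALSE)
  if (!sort) return(sam)
  dest <- sub("\\.bam$", "", out)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
}

#' Parse read-to-contig alignments into alignment segments
#'
#' Reads SAM/BAM (via [Rsamtools::scanBam()]) or PAF with a `cg` CIGAR tag and
#' returns one row per aligned segment with CIGAR-derived coordinates. All
#' coordinates are 0-based half-open; read coordinates are on the forward
#' (original) read strand. Unmapped records are skipped. Secondary alignments
#' are retained with `is_secondary = TRUE` so callers can count them, but every
#' error-calling routine in this package excludes them.
#'
#' @param path Path to a BAM, SAM, or PAF file.
#' @param format `"auto"` infers from the file extension.
#' @return A `data.frame` with columns `read_id`, `contig_id`, `contig_start`,
#'   `contig_end`, `read_start`, `read_end`, `read_len`, `strand`, `mapq`,
#'   `is_primary`, `is_supplementary`, `is_secondary`, `cigar`, `seq` (NA when
#'   the source does not carry sequence, e.g. PAF).
#' @export
parse_alignments <- function(path, format = c("auto", "bam", "sam", "paf")) {
  format <- match.arg(format)
  stop_if_missing_file(path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(sub("\\.gz$", "", path))),
                     bam = "bam", sam = "sam", paf = "paf",
                     stop("cannot infer alignment format from '", path,
                          "'; pass format="))
  }
  if (format == "paf") return(parse_paf_segments(path))
  if (format == "sam") {
    b <- .parse_sam_core(path)
    b$rname <- b$rname  # already character
    keep <- rep(TRUE, length(b$flag))
  } else {
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    b$seq <- as.character(b$seq)
    b$rname <- as.character(b$rname)
    keep <- bitwAnd(b$flag, 4L) == 0L & !is.na(b$pos)
  }
  flag <- b$flag[keep]
  cig <- b$cigar[keep]
  lay <- .cigar_layout(cig)
  strand <- ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")
  rs <- ifelse(strand == "+", lay$clip_left, lay$clip_right)
  data.frame(
    read_id = b$qname[keep],
    contig_id = b$rname[keep],
    contig_start = b$pos[keep] - 1L,
    contig_end = b$pos[keep] - 1L + lay$span,
    read_start = rs,
    read_end = rs + lay$qlen - lay$clip_left - lay$clip_right,
    read_len = lay$qlen,
    strand = strand,
    mapq = b$mapq[keep],
    is_supplementary = bitwAnd(flag, 2048L) != 0L,
    is_secondary = bitwAnd(flag, 256L) != 0L,
    is_primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
    cigar = cig,
    seq = b$seq[keep],
    stringsAsFactors = FALSE
  )
}

## PAF with cg:Z CIGAR; sequence is not carried, so pileup-based small-scale
## calling is unavailable from PAF input (structural calling works).
parse_paf_segments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    return(data.frame(read_id = character(), contig_id = character(),
                      contig_start = integer(), contig_end = integer(),
                      read_start = integer(), read_end = integer(),
                      read_len = integer(), strand = character(),
                      mapq = integer(), is_supplementary = logical(),
                      is_secondary = logical(), is_primary = logical(),
                      cigar = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, `[[`, "", i)
  tagval <- function(tag) vapply(fields, function(f) {
    hit <- f[startsWith(f, tag)]
    if (length(hit) == 0) NA_character_ else sub(tag, "", hit[1], fixed = TRUE)
  }, "")
  cg <- tagval("cg:Z:")
  if (anyNA(cg))
    stop("PAF records lack the cg CIGAR tag; rerun minimap2 with -c ",
         "so the cg:Z tag is emitted", call. = FALSE)
  tp <- tagval("tp:A:")
  data.frame(
    read_id = get(1), contig_id = get(6),
    contig_start = as.integer(get(8)), contig_end = as.integer(get(9)),
    read_start = as.integer(get(3)), read_end = as.integer(get(4)),
    read_len = as.integer(get(2)), strand = get(5),
    mapq = as.integer(get(12)),
    is_supplementary = !is.na(tp) & tp == "S",
    is_secondary = !is.na(tp) & tp == "S" & FALSE, # minimap2 -c: secondaries lack cg
    is_primary = is.na(tp) | tp == "P",
    cigar = cg, seq = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Read-level alignment statistics
#'
#' Summarises read-to-contig alignments: mapping rate (mapped reads / total
#' reads), splitting rate (mapped reads with at least one supplementary
#' segment / mapped reads; a read counts once regardless of how many
#' supplementary segments it has), and mean alignment depth (total aligned
#' contig-span bases divided by total contig bases).
#'
#' @param segments Segment table from [parse_alignments()].
#' @param n_reads Total number of input reads, mapped or not (see
#'   [count_fastx()]).
#' @param total_contig_bases Total assembly length in bp.
#' @return An object of class `read_align_stats`.
#' @export
alignment_stats <- function(segments, n_reads, total_contig_bases) {
  stopifnot(is_scalar_number(n_reads), is_scalar_number(total_contig_bases))
  seg <- segments[!segments$is_secondary, , drop = FALSE]
  mapped <- unique(seg$read_id)
  n_mapped <- length(mapped)
  split_ids <- unique(seg$read_id[seg$is_supplementary])
  n_split <- length(split_ids)
  if (n_reads == 0) warning("zero input reads; rates reported as 0")
  aligned_bases <- sum(as.numeric(seg$contig_end - seg$contig_start))
  structure(list(
    n_reads = as.integer(n_reads),
    n_mapped = n_mapped,
    n_split = n_split,
    mapping_rate = if (n_reads > 0) n_mapped / n_reads else 0,
    splitting_rate = if (n_mapped > 0) n_split / n_mapped else 0,
    mean_depth = if (total_contig_bases > 0) aligned_bases / total_contig_bases else 0
  ), class = "read_align_stats")
}

#' @export
print.read_align_stats <- function(x, ...) {
  cat("Read alignment\n")
  cat(sprintf("  reads:          %d (mapped %d, split %d)\n",
              x$n_reads, x$n_mapped, x$n_split))
  cat(sprintf("  mapping rate:   %.4f\n", x$mapping_rate))
  cat(sprintf("  splitting rate: %.4f\n", x$splitting_rate))
  cat(sprintf("  mean depth:     %.2f\n", x$mean_depth))
  invisible(x)
}

#' Per-position coverage of one contig
#'
#' Position `i` counts non-secondary segments with
#' `contig_start <= i < contig_end` (primary and supplementary alike).
#'
#' @param segments Segment table restricted to one contig.
#' @param contig_length Length of the contig in bp.
#' @return Integer vector of per-position coverage, length `contig_length`.
#' @export
depth_profile <- function(segments, contig_length) {
  seg <- segments[!segments$is_secondary, , drop = FALSE]
  .interval_depth(as.integer(contig_length),
                  as.integer(seg$contig_start), as.integer(seg$contig_end))
}
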