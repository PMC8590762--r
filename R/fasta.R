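#' Read contigs from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that normalises case,
#' trims record names to their first whitespace-delimited token, and enforces
#' name uniqueness. Gzip-compressed files are handled transparently.
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] with one entry per record, in file
#'   order. An empty file yields an empty set.
#' @export
read_fasta <- function(path) {
  stop_if_missing_file(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      line <- first_bad_fasta_line(path)
      stop("malformed FASTA in '", path, "'",
           if (!is.na(line)) paste0(" (around line ", line, ")"),
           ": ", conditionMessage(e), call. = FALSE)
    }
  )
  names(x) <- sub("\\s.*$", "", names(x))
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup) > 0)
    stop("duplicate sequence name(s) in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  Biostrings::DNAStringSet(toupper(x))
}

## Locate the first line that breaks FASTA syntax (sequence before any header).
first_bad_fasta_line <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  seen_header <- FALSE
  i <- 0L
  repeat {
    l <- readLines(con, n = 1L, warn = FALSE)
    if (length(l) == 0) return(NA_integer_)
    i <- i + 1L
    if (!nzchar(trimws(l))) next
    if (startsWith(l, ">")) { seen_header <- TRUE; next }
    if (!seen_header) return(i)
  }
}

#' Write sequences to a FASTA file
#'
#' @param x A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write reads to a FASTQ file with constant base quality
#'
#' @param seqs Named character vector of read sequences.
#' @param path Output path (plain text or `.gz`).
#' @param qual Single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, qual = "I") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  nm <- names(seqs) %||% paste0("read", seq_along(seqs))
  rec <- paste0("@", nm, "\n", seqs, "\n+\n",
                vapply(nchar(seqs), function(n) strrep(qual, n), ""))
  writeLines(rec, con)
  invisible(path)
}

#' Count records and bases in a FASTA/FASTQ file
#'
#' Used to build the read inventory for [alignment_stats()].
#'
#' @param path Path to a FASTA or FASTQ file (gzip ok).
#' @return List with `n_reads` and `total_bases`.
#' @export
count_fastx <- function(path) {
  stop_if_missing_file(path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  first <- readLines(con, n = 1L, warn = FALSE)
  if (length(first) == 0) return(list(n_reads = 0L, total_bases = 0))
  fastq <- startsWith(first, "@")
  close(con); on.exit()
  if (fastq) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
    on.exit(close(con))
    n <- 0L; bases <- 0; i <- 0L
    repeat {
      chunk <- readLines(con, n = 400000L, warn = FALSE)
      if (length(chunk) == 0) break
      idx <- seq_along(chunk) + i
      seqline <- chunk[idx %% 4L == 2L]
      n <- n + length(seqline)
      bases <- bases + sum(nchar(seqline))
      i <- i + length(chunk)
    }
    list(n_reads = n, total_bases = bases)
  } else {
    x <- Biostrings::readDNAStringSet(path)
    list(n_reads = length(x), total_bases = sum(as.numeric(Biostrings::width(x))))
  }
}
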