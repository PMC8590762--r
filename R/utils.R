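`%||%` <- function(x, y) if (is.null(x)) y else x

## N50-style statistic: length of the shortest element at which the
## descending cumulative sum reaches `frac` of `total` (inclusive tie rule).
weighted_nxx <- function(lengths, total = sum(as.numeric(lengths)), frac = 0.5) {
  if (length(lengths) == 0 || total <= 0) return(0L)
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  idx <- which(cumsum(l) >= frac * total)[1]
  if (is.na(idx)) return(0L)
  as.integer(l[idx])
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

## Interval union length of 0-based half-open intervals.
union_length <- function(start0, end0) {
  if (length(start0) == 0) return(0)
  r <- IRanges::reduce(IRanges::IRanges(start = start0 + 1L, end = end0))
  sum(as.numeric(IRanges::width(r)))
}

## names() on an S4 XStringSet can return empty on its very first dispatch
## after deserialisation (lazy method-table initialisation); retry once.
seq_names <- function(x) {
  n <- names(x)
  if (length(x) > 0 && (is.null(n) || length(n) == 0)) n <- names(x)
  n
}

stop_if_missing_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  invisible(path)
}
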