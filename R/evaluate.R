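#' Evaluation parameters
#'
#' Collects the tunable knobs of the evaluator with their defaults. The
#' structural-error boundary is fixed at 50 bp by the error-class definition;
#' the support-ratio cutoff of 0.70 sits between the ~100% expected for true
#' errors and the ~50% expected for heterozygous variants, biased toward
#' precision; the binomial-test settings follow the chemistry (see
#' [small_error_test_params()]).
#'
#' @param datatype One of `"hifi"`, `"clr"`, `"nano"`.
#' @param ... Named overrides of any default.
#' @return A named list of parameters.
#' @export
eval_params <- function(datatype = c("hifi", "clr", "nano"), ...) {
  datatype <- match.arg(datatype)
  tp <- small_error_test_params(datatype)
  defaults <- list(
    datatype = datatype,
    min_structural_size = 50L,   # bp; structural vs small-scale boundary
    min_support = 3L,            # distinct reads per structural candidate
    ratio_cutoff = 0.7,          # min support ratio (error vs het variant)
    depth_cap = 3,               # x mean depth; local-coverage cap
    mq_cutoff = 20,              # min mean mapping quality
    base_window = 500L,          # bp; clustering window floor
    repeat_tolerance_factor = 2, # window scales with cluster size
    min_fraction = 0.2,          # small-scale support pre-filter (inclusive)
    min_depth = 5L,              # min spanning reads for a callable column
    p_err = tp$p_err,            # binomial null support probability
    alpha = tp$alpha,            # binomial significance cut
    flank = 5000L,               # bp; read-collection flank for correction
    anchor = 500L,               # bp; patch-window anchor for correction
    max_consensus_reads = 15L    # reads used by the built-in consensus
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(dots)] <- dots
  defaults
}

#' Evaluate an assembly against its long reads
#'
#' The full reference-free evaluation: continuity statistics, read alignment
#' (or ingestion of precomputed alignments), structural and small-scale error
#' detection, and QV estimation, optionally writing the report and BED files.
#'
#' @param contigs Assembly FASTA path or [Biostrings::DNAStringSet].
#' @param reads Read FASTA/FASTQ path (required unless `alignments` given).
#' @param datatype Sequencing chemistry of the reads.
#' @param alignments Optional precomputed alignment file (BAM/SAM/PAF with
#'   CIGARs) or a parsed segment table; skips the alignment step.
#' @param out_dir Optional output directory for the report.
#' @param params Parameter list from [eval_params()].
#' @param threads Alignment threads.
#' @param keep_segments Keep the parsed segment table in the returned object
#'   (needed by [correct_assembly()]).
#' @param read_inventory Optional list with `n_reads` (skips re-counting the
#'   read file; see [count_fastx()]).
#' @return An object of class `asm_evaluation`: list with `stats`,
#'   `align_stats`, `structural`, `small` (named per-contig list), `qv`,
#'   `params`, and optionally `segments`.
#' @export
evaluate_assembly <- function(contigs, reads = NULL,
                              datatype = c("hifi", "clr", "nano"),
                              alignments = NULL, out_dir = NULL,
                              params = NULL, threads = 1L,
                              keep_segments = FALSE, read_inventory = NULL) {
  datatype <- match.arg(datatype)
  params <- params %||% eval_params(datatype)
  if (!inherits(contigs, "DNAStringSet")) contigs <- read_fasta(contigs)
  stats <- contig_stats(contigs)

  inventory <- read_inventory %||%
    (if (!is.null(reads)) count_fastx(reads) else NULL)
  if (is.null(alignments)) {
    if (is.null(reads)) stop("either reads or alignments must be supplied")
    alignments <- align_reads(reads, contigs, datatype, threads = threads,
                              sort = FALSE)
  }
  segments <- if (is.data.frame(alignments)) alignments
              else parse_alignments(alignments)

  align_stats <- if (!is.null(inventory)) {
    alignment_stats(segments, inventory$n_reads, stats$total_bases)
  } else {
    alignment_stats(segments, length(unique(segments$read_id)),
                    stats$total_bases)
  }

  depth_profiles <- lapply(setNames(seq_names(contigs), seq_names(contigs)), function(cid) {
    depth_profile(segments[segments$contig_id == cid, , drop = FALSE],
                  Biostrings::width(contigs)[match(cid, seq_names(contigs))])
  })

  structural <- detect_structural_errors(segments, contigs, params,
                                         depth_profiles = depth_profiles)

  small <- lapply(setNames(seq_names(contigs), seq_names(contigs)), function(cid) {
    seg <- segments[segments$contig_id == cid, , drop = FALSE]
    detect_small_errors(seg, contigs[[cid]], datatype, params)
  })

  qv <- compute_qv(structural, small, stats$total_bases)
  res <- structure(list(stats = stats, align_stats = align_stats,
                        structural = structural, small = small, qv = qv,
                        params = params, datatype = datatype),
                   class = "asm_evaluation")
  if (keep_segments) res$segments <- segments
  if (!is.null(out_dir))
    write_report(stats, align_stats, structural, small, qv, out_dir)
  res
}

#' @export
print.asm_evaluation <- function(x, ...) {
  print(x$stats)
  if (!is.null(x$align_stats)) print(x$align_stats)
  print(x$qv)
  invisible(x)
}
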