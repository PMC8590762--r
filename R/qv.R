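#' Assembly quality value (QV)
#'
#' Aggregates detected errors into an estimated per-base error rate and a
#' Phred-scaled quality score. The total erroneous bases are
#' `N_Err = N_Exp + N_Col + N_Her + N_Small + n_Inv`: expansions and collapses
#' contribute their sizes, a haplotype switch the larger of its two sides
#' (the base accounting of a two-sided event is otherwise ambiguous), each
#' small-scale error its affected bases (1 for a substitution, the indel
#' length otherwise), and each inversion counts once — an inversion misorders
#' rather than corrupts bases. Then `E = N_Err / N_asm` and
#' `QV = -10 log10(E)`. A zero-error assembly is reported as a lower bound
#' using a pseudo-count of half an error (`qv_lower_bound = TRUE`).
#'
#' @param structural A `structural_errors` data.frame.
#' @param small A `small_scale_errors` data.frame (or a list of them, one per
#'   contig).
#' @param N_asm Total assembly bases; must be positive.
#' @return An object of class `qv_report` with fields `N_Exp`, `N_Col`,
#'   `N_Her`, `N_Small`, `n_Inv`, `N_Err`, `N_asm`, `E`, `QV`,
#'   `qv_lower_bound`, and error counts.
#' @examples
#' compute_qv(NULL, NULL, N_asm = 1e6)  # error-free bound
#' @export
compute_qv <- function(structural, small, N_asm) {
  if (!is_scalar_number(N_asm) || N_asm <= 0)
    stop("N_asm must be a positive number")
  if (is.null(structural)) structural <- filter_structural(empty_clusters(), list(), 0)
  if (is.data.frame(small)) small <- list(small)
  small_sizes <- unlist(lapply(small, function(s) if (is.null(s)) integer() else s$size))
  n_exp <- sum(structural$size_estimate[structural$kind == "Expansion"])
  n_col <- sum(structural$size_estimate[structural$kind == "Collapse"])
  her <- structural[structural$kind == "HaplotypeSwitch", , drop = FALSE]
  n_her <- sum(pmax(her$size_exp, her$size_col))
  n_inv <- sum(structural$kind == "Inversion")
  n_small <- sum(small_sizes)
  n_err <- n_exp + n_col + n_her + n_small + n_inv
  lower_bound <- n_err == 0
  e <- if (lower_bound) 0.5 / N_asm else n_err / N_asm
  structure(list(
    N_Exp = n_exp, N_Col = n_col, N_Her = n_her, N_Small = n_small,
    n_Inv = n_inv, N_Err = n_err, N_asm = N_asm, E = if (lower_bound) 0 else e,
    QV = -10 * log10(e), qv_lower_bound = lower_bound,
    n_structural = nrow(structural), n_small_errors = length(small_sizes)
  ), class = "qv_report")
}

#' @export
print.qv_report <- function(x, ...) {
  cat("Assembly quality\n")
  cat(sprintf("  structural errors:   %d (Exp %d bp, Col %d bp, Her %d bp, Inv %d)\n",
              x$n_structural, x$N_Exp, x$N_Col, x$N_Her, x$n_Inv))
  cat(sprintf("  small-scale errors:  %d (%d bp)\n", x$n_small_errors, x$N_Small))
  cat(sprintf("  error rate:          %.3g\n", x$E))
  cat(sprintf("  QV:                  %s%.2f\n",
              if (x$qv_lower_bound) ">= " else "", x$QV))
  invisible(x)
}

#' Write the evaluation report and BED files
#'
#' Emits a deterministic plain-text summary (`summary.txt`), a JSON twin
#' (`summary.json`), and IGV-loadable BED6+ files for structural
#' (`structural_errors.bed`: contig, start, end, kind, n_support, strand,
#' support_ratio, size, mean_mapq) and small-scale errors
#' (`small_scale_errors.bed`: contig, start, end, kind, n_supp/n_reads,
#' strand, p_value, allele change). Coordinates are 0-based half-open.
#'
#' @param stats [contig_stats()] result.
#' @param align_stats [alignment_stats()] result (or NULL).
#' @param structural `structural_errors` data.frame with a `contig_id` column.
#' @param small Named list (by contig) or single data.frame of
#'   `small_scale_errors`; a `contig_id` column is added from the names.
#' @param qv [compute_qv()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(stats, align_stats, structural, small, qv, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  small_df <- bind_small(small)

  bed1 <- file.path(out_dir, "structural_errors.bed")
  sdf <- as.data.frame(structural)
  if (nrow(sdf) > 0) {
    write.table(data.frame(sdf$contig_id, sdf$start, sdf$end, sdf$kind,
                           sdf$n_support, ".",
                           sprintf("%.4f", sdf$support_ratio),
                           sdf$size_estimate, sprintf("%.1f", sdf$mean_mapq)),
                bed1, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else file.create(bed1)

  bed2 <- file.path(out_dir, "small_scale_errors.bed")
  if (nrow(small_df) > 0) {
    end <- small_df$pos + ifelse(small_df$kind == "SmallCollapse", 1L,
                                 small_df$size)
    write.table(data.frame(small_df$contig_id, small_df$pos, end,
                           small_df$kind,
                           paste0(small_df$n_supp, "/", small_df$n_reads), ".",
                           sprintf("%.3g", small_df$p_value),
                           paste0(small_df$contig_allele, ">",
                                  small_df$read_allele)),
                bed2, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else file.create(bed2)

  per_mbp <- qv$n_small_errors / (qv$N_asm / 1e6)
  lines <- c(
    "# assembly evaluation summary (asmeval)",
    sprintf("n_contigs: %d", stats$n_contigs),
    sprintf("total_bases: %.0f", stats$total_bases),
    sprintf("longest_contig: %d", stats$longest),
    sprintf("second_longest_contig: %d", stats$second_longest),
    sprintf("n50: %d", stats$n50),
    if (!is.null(align_stats)) c(
      sprintf("n_reads: %d", align_stats$n_reads),
      sprintf("mapping_rate: %.4f", align_stats$mapping_rate),
      sprintf("splitting_rate: %.4f", align_stats$splitting_rate),
      sprintf("mean_depth: %.2f", align_stats$mean_depth)),
    sprintf("structural_errors: %d", qv$n_structural),
    sprintf("structural_expansion: %d", sum(structural$kind == "Expansion")),
    sprintf("structural_collapse: %d", sum(structural$kind == "Collapse")),
    sprintf("structural_haplotype_switch: %d",
            sum(structural$kind == "HaplotypeSwitch")),
    sprintf("structural_inversion: %d", sum(structural$kind == "Inversion")),
    sprintf("small_scale_errors: %d", qv$n_small_errors),
    sprintf("small_scale_per_mbp: %.2f", per_mbp),
    sprintf("N_Exp: %d", qv$N_Exp), sprintf("N_Col: %d", qv$N_Col),
    sprintf("N_Her: %d", qv$N_Her), sprintf("N_Small: %d", qv$N_Small),
    sprintf("n_Inv: %d", qv$n_Inv), sprintf("N_Err: %d", qv$N_Err),
    sprintf("error_rate: %.6g", qv$E),
    sprintf("qv: %s%.2f", if (qv$qv_lower_bound) ">=" else "", qv$QV))
  writeLines(lines, file.path(out_dir, "summary.txt"))

  json <- list(continuity = unclass(stats),
               read_alignment = if (!is.null(align_stats)) unclass(align_stats),
               errors = unclass(qv), small_scale_per_mbp = per_mbp)
  jsonlite::write_json(json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

bind_small <- function(small) {
  if (is.null(small)) small <- list()
  if (is.data.frame(small)) small <- list(small)
  parts <- lapply(names(small) %||% seq_along(small), function(nm) {
    s <- small[[nm]]
    if (is.null(s) || nrow(s) == 0) return(NULL)
    if (is.null(s$contig_id)) s$contig_id <- as.character(nm)
    s
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (length(parts) == 0) {
    return(data.frame(contig_id = character(), pos = integer(),
                      kind = character(), size = integer(),
                      n_reads = integer(), n_supp = integer(),
                      support_fraction = numeric(), p_value = numeric(),
                      alt_base = character(), contig_allele = character(),
                      read_allele = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
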