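## Simulation benchmark: synthetic diploid genomes with SNPs and indel SVs,
## assemblies with spiked structural and small-scale errors, long reads with
## CLR-like or HiFi-like error profiles, and truth-set scoring.

#' Simulation configuration
#'
#' Defaults define the package's benchmark study conditions: a 5-Mb diploid
#' genome carrying SNPs at 3.2e-4/bp and indel SVs at 3.2e-5/bp (67%
#' heterozygous), an assembly built from haplotype 1 with 16 spiked
#' structural errors (7 expansions, 7 collapses, 1 haplotype switch, 1
#' inversion; ten times fewer than the SVs they must be distinguished from)
#' and 950 small-scale errors (50% base substitutions, 25% 1-bp expansions,
#' 25% 1-bp collapses; 1.9e-4/bp), and 50x long reads of mean length 15,000
#' (sd 3,000) with 2% (HiFi-like) or 15% (CLR-like) error.
#'
#' @param genome_length Random-genome length in bp (before N gaps).
#' @param n_gaps,gap_len N runs inserted into the genome; the assembly splits
#'   into contigs at these.
#' @param n_snp,n_sv Variant counts.
#' @param het_fraction Fraction of variants assigned heterozygous.
#' @param sv_ins_fraction Fraction of SVs that are insertions.
#' @param sv_size_geom_mean,sv_min_size,sv_max_size Geometric-like SV/error
#'   size spectrum: `min + rgeom(mean)` capped at `max`.
#' @param error_composition Named counts of spiked structural errors
#'   (`expansion`, `collapse`, `haplotype_switch`, `inversion`).
#' @param n_small_errors,small_mix Spiked small-scale errors and their mix
#'   (`sub`, `exp`, `col`).
#' @param inv_size_range Inversion size range in bp (uniform).
#' @param read_depth,read_length_mean,read_length_sd,read_length_min Read
#'   sampling parameters.
#' @param read_accuracy Named per-chemistry mean base accuracy.
#' @param error_mix Named per-chemistry substitution/insertion/deletion split
#'   of the read error rate (CLR indel-rich, HiFi substitution-leaning).
#' @param min_frag Assembly fragments shorter than this are dropped after
#'   splitting at N runs.
#' @param margin Spikes and variants keep this distance from sequence ends
#'   and N gaps (read coverage ramps near boundaries).
#' @param struct_spacing Minimum distance between structural loci.
#' @param ploidy `"diploid"` or `"haploid"` (haploid: all variants
#'   homozygous, reads from haplotype 1 only, no haplotype switches).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 5e6, n_gaps = 4L, gap_len = 100L,
                       n_snp = 1600L, n_sv = 160L, het_fraction = 0.67,
                       sv_ins_fraction = 0.5, sv_size_geom_mean = 250,
                       sv_min_size = 50L, sv_max_size = 2000L,
                       error_composition = c(expansion = 7L, collapse = 7L,
                                             haplotype_switch = 1L,
                                             inversion = 1L),
                       n_small_errors = 950L,
                       small_mix = c(sub = 0.5, exp = 0.25, col = 0.25),
                       inv_size_range = c(500L, 2500L),
                       read_depth = 50, read_length_mean = 15000,
                       read_length_sd = 3000, read_length_min = 1000,
                       read_accuracy = c(clr = 0.85, hifi = 0.98, nano = 0.85),
                       error_mix = list(
                         hifi = c(sub = 0.5, ins = 0.25, del = 0.25),
                         clr = c(sub = 0.1, ins = 0.6, del = 0.3),
                         nano = c(sub = 0.4, ins = 0.3, del = 0.3)),
                       min_frag = 10000L, margin = 20000L,
                       struct_spacing = 2000L,
                       ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  if (ploidy == "haploid") {
    het_fraction <- 0
    error_composition["expansion"] <- error_composition["expansion"] +
      error_composition["haplotype_switch"]
    error_composition["haplotype_switch"] <- 0L
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Random genome with N gaps
#'
#' @param config A [sim_config()].
#' @return Character scalar genome sequence (uses the current RNG state; call
#'   `set.seed()` first for reproducibility).
#' @export
random_genome <- function(config) {
  g <- .random_dna(as.integer(config$genome_length))
  if (config$n_gaps > 0) {
    L <- nchar(g)
    at <- round(L * seq_len(config$n_gaps) / (config$n_gaps + 1))
    edits <- data.frame(pos0 = as.integer(at), ref_len = 0L,
                        alt = strrep("N", config$gap_len),
                        stringsAsFactors = FALSE)
    g <- apply_edits(g, edits)
  }
  g
}

## --- coordinate-shift machinery ---------------------------------------------
## An edit replaces [pos0, pos0 + ref_len) with `alt` (0-based source coords).
## Edits must be sorted and non-overlapping.

apply_edits <- function(seq, edits) {
  if (nrow(edits) == 0) return(seq)
  e <- edits[order(edits$pos0), , drop = FALSE]
  if (any(e$pos0[-1] < (e$pos0 + e$ref_len)[-nrow(e)]))
    stop("overlapping edits")
  starts <- c(1L, e$pos0 + e$ref_len + 1L)
  ends <- c(e$pos0, nchar(seq))
  pieces <- substring(seq, starts, ends)
  paste0(paste0(pieces[-length(pieces)], e$alt, collapse = ""),
         pieces[length(pieces)])
}

## Map source positions (outside any edit) to post-edit coordinates. An edit
## counts as "before" pos when its source footprint ends at or before pos; a
## zero-length insertion anchored exactly at pos is NOT before it (the
## inserted sequence lands at pos, so pos itself keeps its coordinate).
shift_positions <- function(pos, edits) {
  if (nrow(edits) == 0 || length(pos) == 0) return(pos)
  e <- edits[order(edits$pos0), , drop = FALSE]
  delta <- cumsum(nchar(e$alt) - e$ref_len)
  bound <- e$pos0 + e$ref_len
  idx <- findInterval(pos, bound)
  self_ins <- idx > 0 & bound[pmax(idx, 1)] == pos &
    e$ref_len[pmax(idx, 1)] == 0L
  idx <- idx - self_ins
  pos + ifelse(idx > 0, delta[pmax(idx, 1)], 0)
}

## Sample `n` loci of `width` bp avoiding forbidden intervals and keeping
## pairwise spacing; errors out when the genome cannot host the request.
sample_loci <- function(n, L, avoid, spacing, width = 1L) {
  if (n == 0) return(integer())
  if (nrow(avoid) > 0) {  # merge overlaps so the binary-search check is exact
    r <- IRanges::reduce(IRanges::IRanges(start = avoid$start + 1L,
                                          end = pmax(avoid$end, avoid$start)))
    avoid <- data.frame(start = IRanges::start(r) - 1L, end = IRanges::end(r))
  }
  chosen <- integer()
  tries <- 0L
  max_tries <- 500L * n + 1000L
  while (length(chosen) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("cannot place ", n, " loci of width ", width,
           " with spacing ", spacing, " in ", L, " bp; genome too small ",
           "for the requested counts")
    p <- as.integer(floor(runif(1) * (L - width)))
    if (nrow(avoid) > 0) {
      i <- findInterval(p + width, avoid$start)
      ## overlaps avoid[i] if p < avoid$end[i]
      if (i > 0 && p < avoid$end[i]) next
    }
    if (length(chosen) > 0 && min(abs(chosen - p)) < spacing + width) next
    chosen <- c(chosen, p)
  }
  sort(chosen)
}

## Geometric-like structural size spectrum.
sv_sizes <- function(n, config) {
  s <- config$sv_min_size +
    stats::rgeom(n, 1 / (config$sv_size_geom_mean - config$sv_min_size + 1))
  pmin(s, config$sv_max_size)
}

forbidden_margins <- function(seq, margin) {
  L <- nchar(seq)
  gaps <- gregexpr("N+", seq)[[1]]
  iv <- data.frame(start = integer(), end = integer())
  if (gaps[1] != -1) {
    gl <- attr(gaps, "match.length")
    iv <- data.frame(start = as.integer(gaps) - 1L - margin,
                     end = as.integer(gaps) - 1L + gl + margin)
  }
  rbind(iv,
        data.frame(start = c(0L, L - margin), end = c(margin, L)))
}

#' Simulate a diploid genome
#'
#' Generates a random genome, places SNPs and indel SVs uniformly without
#' overlap, assigns exactly `round(het_fraction * n)` of each variant class
#' heterozygous by a seeded shuffle (heterozygous variants go to one randomly
#' chosen haplotype, homozygous to both), and applies them to produce the two
#' haplotypes.
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `hap1`, `hap2` (character), `variants`
#'   (genome-coordinate table with `pos`, `type`, `size`, `alt`, `zygosity`,
#'   `hap`), and per-haplotype edit tables used for coordinate projection.
#' @export
simulate_diploid <- function(config) {
  g <- random_genome(config)
  L <- nchar(g)
  avoid0 <- forbidden_margins(g, config$margin)

  sv_pos <- sample_loci(config$n_sv, L, avoid0, config$struct_spacing,
                        width = config$sv_max_size + 1L)
  sizes <- sv_sizes(config$n_sv, config)
  is_ins <- runif(config$n_sv) < config$sv_ins_fraction
  sv <- data.frame(pos = sv_pos, type = ifelse(is_ins, "ins", "del"),
                   size = as.integer(sizes), stringsAsFactors = FALSE)
  sv$alt <- ifelse(sv$type == "ins",
                   vapply(sv$size, .random_dna, ""), "")

  sv_iv <- data.frame(start = sv$pos - 10L, end = sv$pos + sv$size + 10L)
  snp_pos <- sample_loci(config$n_snp, L, rbind(avoid0, sv_iv), 10L)
  if (config$n_snp > 0) {
    ref <- substring(g, snp_pos + 1L, snp_pos + 1L)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  "", USE.NAMES = FALSE)
    snp <- data.frame(pos = snp_pos, type = "snp", size = 1L, alt = alt,
                      stringsAsFactors = FALSE)
  } else {
    snp <- sv[0, c("pos", "type", "size", "alt")]
  }

  assign_zyg <- function(v) {
    n <- nrow(v)
    n_het <- round(config$het_fraction * n)
    het <- rep(FALSE, n)
    het[sample(n, n_het)] <- TRUE
    v$zygosity <- ifelse(het, "het", "hom")
    v$hap <- ifelse(het, sample(c(1L, 2L), n, replace = TRUE), 0L)
    v
  }
  sv <- assign_zyg(sv)
  snp <- assign_zyg(snp)
  variants <- rbind(sv, snp)
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL

  edits_for <- function(hap) {
    v <- variants[variants$hap %in% c(0L, hap), , drop = FALSE]
    data.frame(pos0 = v$pos,
               ref_len = ifelse(v$type == "del", v$size,
                                ifelse(v$type == "snp", 1L, 0L)),
               alt = v$alt, stringsAsFactors = FALSE)
  }
  e1 <- edits_for(1L); e2 <- edits_for(2L)
  list(genome = g, hap1 = apply_edits(g, e1),
       hap2 = if (config$ploidy == "haploid") NULL else apply_edits(g, e2),
       variants = variants, hap1_edits = e1, hap2_edits = e2,
       config = config)
}

## Variant footprint intervals in haplotype-1 coordinates (used to keep
## spiked errors away from variant loci). SNPs cannot mimic structural
## signals, so they get a small pad; SV loci get the full structural pad.
variant_intervals_hap1 <- function(sim, pad = 0L, pad_snp = pad) {
  v <- sim$variants
  if (nrow(v) == 0) return(data.frame(start = integer(), end = integer()))
  p1 <- shift_positions(v$pos, sim$hap1_edits)
  span <- ifelse(v$type == "snp", 1L,
          ifelse(v$type == "ins",
                 ifelse(v$hap %in% c(0L, 1L), v$size, 1L),
                 ifelse(v$hap %in% c(0L, 1L), 1L, v$size)))
  p <- ifelse(v$type == "snp", pad_snp, pad)
  data.frame(start = p1 - p, end = p1 + span + p)
}

#' Spike assembly errors into a haplotype
#'
#' Builds the simulated assembly: structural errors (expansions insert novel
#' sequence, collapses delete sequence, inversions reverse-complement a
#' segment, haplotype switches replace a heterozygous insertion SV carried by
#' haplotype 1 with only its first half, so reads from either haplotype
#' disagree with the contig by at least 50 bp in opposite directions) and
#' small-scale errors (base substitutions, 1-bp expansions, 1-bp collapses)
#' are applied to haplotype 1 with at least `struct_spacing` bp between
#' structural loci, keeping clear of variant loci so the truth set is
#' unambiguous. The edited sequence is split into contigs at N runs and
#' fragments shorter than `min_frag` are dropped.
#'
#' @param sim Output of [simulate_diploid()].
#' @param composition Named structural-error counts (defaults from the
#'   config).
#' @param n_small Number of small-scale errors (default from the config).
#' @return List with `assembly` ([Biostrings::DNAStringSet] of contigs),
#'   `truth_structural`, `truth_small`, and `variants_assembly` (variant loci
#'   in assembly/contig coordinates), each with `contig_id`, `start`/`pos`,
#'   `kind`, `size` columns.
#' @export
spike_errors <- function(sim, composition = NULL, n_small = NULL) {
  config <- sim$config
  composition <- composition %||% config$error_composition
  n_small <- n_small %||% config$n_small_errors
  hap1 <- sim$hap1
  L <- nchar(hap1)
  avoid0 <- forbidden_margins(hap1, config$margin)
  var_iv <- variant_intervals_hap1(sim, pad = config$struct_spacing,
                                   pad_snp = 50L)

  n_exp <- composition[["expansion"]] %||% 0L
  n_col <- composition[["collapse"]] %||% 0L
  n_swi <- composition[["haplotype_switch"]] %||% 0L
  n_inv <- composition[["inversion"]] %||% 0L

  ## haplotype switches sit at existing het insertion SVs carried by hap1
  switch_edits <- NULL
  if (n_swi > 0) {
    v <- sim$variants
    elig <- which(v$type == "ins" & v$zygosity == "het" & v$hap == 1L &
                    v$size >= 100L)
    if (length(elig) < n_swi)
      stop("not enough heterozygous hap1 insertion SVs (>= 100 bp) to host ",
           n_swi, " haplotype switches")
    pick <- v[elig[sample.int(length(elig), n_swi)], , drop = FALSE]
    p1 <- shift_positions(pick$pos, sim$hap1_edits)
    half <- as.integer(floor(pick$size / 2))
    switch_edits <- data.frame(
      pos0 = p1, ref_len = pick$size,
      alt = substring(hap1, p1 + 1L, p1 + half),
      kind = "HaplotypeSwitch", size = pmax(half, pick$size - half),
      size_exp = half, size_col = pick$size - half,
      stringsAsFactors = FALSE)
  }

  n_other <- n_exp + n_col + n_inv
  avoid_struct <- rbind(avoid0, var_iv)
  pos <- sample_loci(n_other, L, avoid_struct, config$struct_spacing,
                     width = config$sv_max_size + 1L)
  pos <- pos[sample.int(length(pos))]  # random assignment of kinds to loci
  kinds <- c(rep("Expansion", n_exp), rep("Collapse", n_col),
             rep("Inversion", n_inv))
  sizes <- integer(n_other)
  sizes[kinds != "Inversion"] <- sv_sizes(sum(kinds != "Inversion"), config)
  if (n_inv > 0)
    sizes[kinds == "Inversion"] <- as.integer(round(runif(
      n_inv, config$inv_size_range[1], config$inv_size_range[2])))
  struct_edits <- data.frame(
    pos0 = pos,
    ref_len = ifelse(kinds == "Expansion", 0L, sizes),
    alt = rep(NA_character_, n_other), kind = kinds, size = sizes,
    size_exp = ifelse(kinds == "Expansion", sizes, NA_integer_),
    size_col = ifelse(kinds == "Collapse", sizes, NA_integer_),
    stringsAsFactors = FALSE)
  struct_edits$alt <- ifelse(
    kinds == "Expansion", vapply(sizes, .random_dna, ""),
    ifelse(kinds == "Collapse", "",
           vapply(seq_len(n_other), function(i) {
             if (kinds[i] != "Inversion") return("")
             revcomp_chr(substring(hap1, pos[i] + 1L, pos[i] + sizes[i]))
           }, "")))
  if (!is.null(switch_edits))
    struct_edits <- rbind(struct_edits,
                          switch_edits[, names(struct_edits), drop = FALSE])

  ## small-scale errors avoid variants and structural loci
  struct_iv <- data.frame(start = struct_edits$pos0 - 500L,
                          end = struct_edits$pos0 + struct_edits$ref_len + 500L)
  var_iv_s <- variant_intervals_hap1(sim, pad = 10L)
  n_sub <- round(n_small * config$small_mix[["sub"]])
  n_sexp <- round(n_small * config$small_mix[["exp"]])
  n_scol <- n_small - n_sub - n_sexp
  spos <- sample_loci(n_small, L, rbind(avoid0, var_iv_s, struct_iv), 10L,
                      width = 2L)
  spos <- spos[sample.int(length(spos))]
  skind <- c(rep("BaseSubstitution", n_sub), rep("SmallExpansion", n_sexp),
             rep("SmallCollapse", n_scol))
  sref <- if (n_small > 0) substring(hap1, spos + 1L, spos + 1L) else character()
  salt <- vapply(seq_len(n_small), function(i) {
    switch(skind[i],
           BaseSubstitution = sample(setdiff(c("A", "C", "G", "T"), sref[i]), 1),
           SmallExpansion = .random_dna(1L),  # extra base in the contig
           SmallCollapse = "")                # contig misses this base
  }, "")
  small_edits <- data.frame(
    pos0 = spos,
    ref_len = ifelse(skind == "BaseSubstitution", 1L,
                     ifelse(skind == "SmallCollapse", 1L, 0L)),
    alt = salt,  # SmallExpansion inserts one extra base before pos0
    kind = skind, size = rep(1L, n_small), stringsAsFactors = FALSE)

  all_edits <- rbind(struct_edits[, c("pos0", "ref_len", "alt")],
                     small_edits[, c("pos0", "ref_len", "alt")])
  assembly_seq <- apply_edits(hap1, all_edits)

  to_asm <- function(p) shift_positions(p, all_edits)
  truth_structural <- data.frame(
    start = to_asm(struct_edits$pos0),
    kind = struct_edits$kind, size = struct_edits$size,
    size_exp = struct_edits$size_exp, size_col = struct_edits$size_col,
    stringsAsFactors = FALSE)
  truth_structural$end <- truth_structural$start +
    ifelse(truth_structural$kind == "Collapse", 0L,
           nchar(struct_edits$alt))
  truth_small <- data.frame(
    pos = to_asm(small_edits$pos0), kind = small_edits$kind,
    size = rep(1L, n_small), stringsAsFactors = FALSE)

  v <- sim$variants
  variants_assembly <- data.frame(
    pos = to_asm(shift_positions(v$pos, sim$hap1_edits)),
    type = v$type, size = v$size, zygosity = v$zygosity, hap = v$hap,
    stringsAsFactors = FALSE)

  split_into_contigs(assembly_seq, config$min_frag,
                     truth_structural, truth_small, variants_assembly)
}

## Split the edited haplotype at N runs, drop short fragments, and project
## all truth coordinates into contig space.
split_into_contigs <- function(seq, min_frag, truth_structural, truth_small,
                               variants_assembly) {
  gaps <- gregexpr("N{10,}", seq)[[1]]
  if (gaps[1] == -1) {
    starts <- 0L; ends <- nchar(seq)
  } else {
    gs <- as.integer(gaps) - 1L
    ge <- gs + attr(gaps, "match.length")
    starts <- c(0L, ge); ends <- c(gs, nchar(seq))
  }
  keep <- (ends - starts) >= min_frag
  starts <- starts[keep]; ends <- ends[keep]
  ids <- paste0("ctg", seq_along(starts))
  contigs <- Biostrings::DNAStringSet(substring(seq, starts + 1L, ends))
  names(contigs) <- ids

  locate <- function(pos) {
    i <- findInterval(pos, starts)
    inside <- i > 0 & pos < ends[pmax(i, 1)]
    list(contig_id = ifelse(inside, ids[pmax(i, 1)], NA_character_),
         pos = ifelse(inside, pos - starts[pmax(i, 1)], NA_integer_))
  }
  ls <- locate(truth_structural$start)
  truth_structural$contig_id <- ls$contig_id
  truth_structural$end <- truth_structural$end - truth_structural$start +
    ls$pos
  truth_structural$start <- ls$pos
  truth_structural <- truth_structural[!is.na(truth_structural$contig_id), ,
                                       drop = FALSE]
  lm <- locate(truth_small$pos)
  truth_small$contig_id <- lm$contig_id
  truth_small$pos <- lm$pos
  truth_small <- truth_small[!is.na(truth_small$contig_id), , drop = FALSE]
  lv <- locate(variants_assembly$pos)
  variants_assembly$contig_id <- lv$contig_id
  variants_assembly$pos <- lv$pos
  variants_assembly <- variants_assembly[!is.na(variants_assembly$contig_id), ,
                                         drop = FALSE]
  list(assembly = contigs, truth_structural = truth_structural,
       truth_small = truth_small, variants_assembly = variants_assembly)
}

#' Simulate long reads from haplotypes
#'
#' Samples reads with normally distributed lengths (truncated at
#' `read_length_min`), uniform start positions, random strand, and i.i.d.
#' per-base errors at the chemistry's rate split into substitutions, 1-bp
#' insertions, and deletions. Depth is divided evenly across haplotypes.
#'
#' @param haps List of haplotype sequences (character).
#' @param config A [sim_config()].
#' @param datatype Chemistry preset for accuracy and error mix.
#' @param path Output FASTQ path (constant quality).
#' @return List with `path`, `n_reads`, `total_bases`.
#' @export
simulate_reads <- function(haps, config, datatype = c("hifi", "clr", "nano"),
                           path = tempfile(fileext = ".fq")) {
  datatype <- match.arg(datatype)
  e <- 1 - config$read_accuracy[[datatype]]
  mix <- config$error_mix[[datatype]]
  mix <- mix / sum(mix)
  all_seqs <- character(0)
  for (h in seq_along(haps)) {
    target <- config$read_depth * nchar(haps[[h]]) / length(haps)
    rd <- .sim_reads_core(haps[[h]], target, config$read_length_mean,
                          config$read_length_sd,
                          as.integer(config$read_length_min),
                          e * mix[["sub"]], e * mix[["ins"]], e * mix[["del"]])
    nm <- sprintf("h%d_%06d_%d_%s", h, seq_along(rd$seq), rd$start,
                  ifelse(rd$forward, "f", "r"))
    seqs <- setNames(rd$seq, nm)
    all_seqs <- c(all_seqs, seqs)
  }
  write_fastq(all_seqs, path)
  list(path = path, n_reads = length(all_seqs),
       total_bases = sum(nchar(all_seqs)))
}

#' Score calls against a spiked truth set
#'
#' One-to-one greedy matching by breakpoint distance. A structural call
#' matches a truth record of compatible kind (equal kinds, or a haplotype
#' switch on either side matching expansion/collapse/switch) when start
#' positions are within `match_window` bp and sizes agree reciprocally within
#' `size_tolerance` (the size test is waived when either side is a switch; an
#' unknown-size side always passes). A small-scale call matches on equal kind
#' within `small_window` bp (alignment indel normalisation can shift 1-bp
#' indel coordinates by a few bases).
#'
#' @param calls Call table (`structural_errors` or combined small-scale table
#'   with `contig_id` and `pos`).
#' @param truth Truth table from [spike_errors()].
#' @param class `"structural"` or `"small"`.
#' @param match_window,size_tolerance,small_window Matching tolerances.
#' @return An object of class `benchmark_result`: `tp`, `fp`, `fn`, `recall`,
#'   `precision`, `f1` (precision is `NaN` and f1 0 when there are no
#'   calls).
#' @export
score_calls <- function(calls, truth, class = c("structural", "small"),
                        match_window = 500L, size_tolerance = 0.5,
                        small_window = 5L) {
  class <- match.arg(class)
  if (class == "small") {
    calls$start <- calls$pos
    truth$start <- truth$pos
    window <- small_window
  } else {
    if (is.null(calls$size) && !is.null(calls$size_estimate))
      calls$size <- calls$size_estimate
    window <- match_window
  }
  nc <- nrow(calls); nt <- nrow(truth)
  if (nc == 0) {
    return(structure(list(tp = 0L, fp = 0L, fn = nt, recall = 0,
                          precision = NaN, f1 = 0), class = "benchmark_result"))
  }
  pairs <- list()
  for (i in seq_len(nc)) {
    cand <- which(truth$contig_id == calls$contig_id[i] &
                    abs(truth$start - calls$start[i]) <= window)
    for (j in cand) {
      if (class == "structural") {
        kc <- calls$kind[i]; kt <- truth$kind[j]
        compat <- kc == kt ||
          (kc == "HaplotypeSwitch" && kt %in% c("Expansion", "Collapse")) ||
          (kt == "HaplotypeSwitch" && kc %in% c("Expansion", "Collapse"))
        if (!compat) next
        if (kc != "HaplotypeSwitch" && kt != "HaplotypeSwitch") {
          s1 <- calls$size[i]; s2 <- truth$size[j]
          if (!is.na(s1) && !is.na(s2) && s1 > 0 && s2 > 0 &&
              min(s1, s2) / max(s1, s2) < size_tolerance) next
        }
      } else {
        if (calls$kind[i] != truth$kind[j]) next
      }
      pairs[[length(pairs) + 1]] <- c(i, j, abs(truth$start[j] - calls$start[i]))
    }
  }
  tp <- 0L
  if (length(pairs) > 0) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, 3]), , drop = FALSE]
    used_c <- logical(nc); used_t <- logical(nt)
    for (k in seq_len(nrow(pm))) {
      i <- pm[k, 1]; j <- pm[k, 2]
      if (used_c[i] || used_t[j]) next
      used_c[i] <- TRUE; used_t[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- nc - tp; fn <- nt - tp
  recall <- if (nt > 0) tp / nt else NaN
  precision <- tp / nc
  f1 <- if (!is.nan(recall) && !is.nan(precision) && (recall + precision) > 0)
    2 * recall * precision / (recall + precision) else 0
  structure(list(tp = tp, fp = fp, fn = fn, recall = recall,
                 precision = precision, f1 = f1), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | recall %.4f  precision %.4f  F1 %.4f\n",
              x$tp, x$fp, x$fn, x$recall, x$precision, x$f1))
  invisible(x)
}

#' Run the full simulation benchmark once
#'
#' Simulates a diploid (or haploid) genome, spikes assembly errors, simulates
#' reads, runs the complete evaluation, and scores structural and small-scale
#' calls against the spiked truth.
#'
#' @param seed RNG seed (the run is a pure function of seed and config).
#' @param datatype Read chemistry.
#' @param config A [sim_config()].
#' @param dir Working directory for FASTA/FASTQ/BAM intermediates.
#' @param threads Alignment threads.
#' @param keep_segments Keep parsed segments in the evaluation (for
#'   correction experiments).
#' @return List with `evaluation`, `structural_score`, `small_score`, `sim`
#'   (truth tables and variant loci), and file paths.
#' @export
run_benchmark <- function(seed, datatype = c("hifi", "clr", "nano"),
                          config = sim_config(), dir = tempfile("bench"),
                          threads = 1L, keep_segments = FALSE) {
  datatype <- match.arg(datatype)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  sim <- simulate_diploid(config)
  spiked <- spike_errors(sim)
  asm_path <- file.path(dir, "assembly.fa")
  write_fasta(spiked$assembly, asm_path)
  haps <- if (config$ploidy == "haploid") list(sim$hap1)
          else list(sim$hap1, sim$hap2)
  reads <- simulate_reads(haps, config, datatype,
                          path = file.path(dir, "reads.fq"))
  ev <- evaluate_assembly(spiked$assembly, reads$path, datatype,
                          threads = threads, keep_segments = keep_segments,
                          read_inventory = reads)
  small_calls <- bind_small(ev$small)
  list(evaluation = ev,
       structural_score = score_calls(ev$structural, spiked$truth_structural,
                                      "structural"),
       small_score = score_calls(small_calls, spiked$truth_small, "small"),
       truth_structural = spiked$truth_structural,
       truth_small = spiked$truth_small,
       variants_assembly = spiked$variants_assembly,
       assembly = spiked$assembly,
       assembly_path = asm_path, reads_path = reads$path, seed = seed,
       datatype = datatype, config = config)
}
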