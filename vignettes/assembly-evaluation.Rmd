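---
title: "Reference-free assembly evaluation: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free assembly evaluation: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`asmeval` evaluates a long-read de novo assembly against the reads it was
built from. This vignette explains the statistical model behind each stage,
the parameters that matter and why their defaults are what they are, what
the built-in simulator does and does not emulate, and the numerical and
design choices made where several reasonable options existed.

## 1. Why reads, not a reference

A reference genome from another individual differs from the sequenced
sample by genuine variants — hundreds of thousands of SNPs and tens of
thousands of structural variants for a human — so contig-to-reference
discrepancies mix assembly mistakes with biology. Reads sampled from the
sequenced genome do not have this problem. The price is that reads carry
sequencing error, so every decision below is about separating three
signals: assembly errors (all reads disagree with the contig), heterozygous
variants (about half disagree), and sequencing noise (a small, roughly
independent fraction disagrees at any one position).

## 2. Structural errors (≥ 50 bp)

### Signals

Every non-secondary alignment is scanned for:

* **Expansion** — a deletion run (`D`) of ≥ 50 bp: the contig contains
  sequence the read skips.
* **Collapse** — an insertion run (`I`) of ≥ 50 bp: the read carries
  sequence the contig lacks.
* **Split-read gaps** — when one read aligns in several segments on one
  contig, a disagreement of ≥ 50 bp between the contig-coordinate gap and
  the read-coordinate gap between consecutive same-strand segments is an
  expansion (contig gap larger) or collapse (read gap larger). This catches
  events too large for the aligner to represent inside one CIGAR.
* **Inversion** — a read aligning in ≥ 3 segments with a strand flip; the
  minority-strand segment is the inverted block. Two-segment flips are
  ignored: with reads sampled from both genomic strands there is no way to
  tell which of the two segments is the inverted one, and a real inversion
  at usable coverage always yields fully spanning three-segment reads.

Secondary alignments are excluded everywhere; supplementary alignments are
kept because split reads carry the gap and inversion signals. This mirrors
standard SV-calling practice.

### Clustering

Signals of one type on one contig are sorted by position and clustered
greedily: a signal joins the open cluster if it lies within
`max(base_window, repeat_tolerance_factor × median cluster size)` of the
cluster's rightmost member. The `base_window` floor (500 bp) absorbs
ordinary breakpoint jitter; scaling the window with the running size
estimate tolerates the larger shifts that repeat copies induce — a signal
displaced by one repeat unit moves by about the event size — while keeping
the window tight in unique sequence. A read counts once per cluster however
many signals it contributes.

### Haplotype switches

At a heterozygous SV the assembler may emit a sequence matching neither
haplotype; reads from one haplotype then signal a collapse and reads from
the other an expansion at the same locus. Expansion and collapse clusters
whose padded intervals overlap are merged into one haplotype-switch
candidate, nearest midpoints first, each cluster consumed at most once. The
switch's support is the union of both sides' reads — this is deliberate:
individually each side sits near 50% support and would be (correctly)
filtered as a variant, but jointly they approach 100%, which is exactly the
error signature.

### The variant filter

A candidate becomes a call iff

* `n_support ≥ 3` distinct reads — removes isolated alignment artifacts;
* `support_ratio ≥ 0.70` — the key error-vs-variant discriminator. Theory
  puts errors near 100% and heterozygous variants near 50%; 0.70 sits
  between them, biased toward precision because at usable depth (≥ 30×)
  the sampling spread of a 50% locus rarely reaches 0.70 while true errors
  rarely fall below 0.85. Exposed as `ratio_cutoff`.
* local coverage ≤ 3× the assembly mean (`depth_cap`) — collapsed-repeat
  regions attract reads from many copies and produce unreliable signals;
* mean mapping quality ≥ 20 (`mq_cutoff`).

Local coverage is the mean depth over the candidate interval padded by
50 bp, using primary plus supplementary segments.

## 3. Small-scale errors (< 50 bp)

Per contig position the pileup records the spanning-read depth, per-base
counts, small-deletion counts, and insertion counts anchored at the base
preceding the insertion. Indel runs of ≥ 50 bp belong to the structural
class and are excluded from these tallies. The most-supported alternative
event per column becomes a candidate iff its support fraction is ≥ 0.20
(inclusive — exactly 20% is kept) and the column has ≥ 5 spanning reads
(`min_depth`; shallower columns are uncallable rather than confidently
clean). Trials in the binomial model are *spanning* reads only: a read
whose alignment is clipped before the column never observed it.

The one-tailed binomial test asks whether the support fraction is too high
for a heterozygous variant: `p_value = Σ_{i=n_supp}^{n_reads}
Binomial(i | p, n_reads)` computed as an exact upper tail. For accurate
HiFi reads a read from the variant haplotype shows the alternative allele
essentially always, so the null is p = 0.5 with significance 0.01. CLR and
Nanopore reads lose 15–20% of per-read support to sequencing error, so the
null drops to p = 0.4 and the cut relaxes to 0.05. Per-site thresholds are
used as-is, without multiple-testing correction: the thresholds are part of
the method's definition and the 20% pre-filter already removes the bulk of
the noise hypotheses.

One candidate per column (the top alternative) is deliberate: at consensus
level a position has one correct answer, and lesser alternatives at the
same site are dominated by sequencing noise. Runs of adjacent
deletion-candidates merge into one multi-base event.

## 4. Quality value

`N_Err = N_Exp + N_Col + N_Her + N_Small + n_Inv`, `E = N_Err / N_asm`,
`QV = −10 log10 E`. Expansions and collapses contribute their sizes and
small-scale errors their affected bases. A haplotype switch contributes the
**larger** of its two sides: the event misrepresents one locus, and the
larger side bounds the bases that differ from the nearest true haplotype
(the accounting of a two-sided event is otherwise ambiguous; this choice is
explicit rather than inherited). An inversion contributes 1, not its
length: its bases are present and correct, only their orientation is wrong,
so counting the full span would let a single large inversion dominate the
genome-wide base-accuracy estimate. An error-free assembly reports a lower
bound computed from a pseudo-count of half an error, flagged with `≥`
rather than an infinite QV.

## 5. Correction

Small-scale errors are rewritten to the majority read allele, applied
right-to-left so coordinates stay valid; overlapping calls keep the lower
p-value.

Structural errors are patched from a local consensus. The patch window is
the error interval padded by `anchor = 500` bp on each side. Each
supporting read's subsequence spanning the window is extracted by mapping
the window boundaries through the read's CIGAR — the reads are already
aligned, so no anchor search is needed, and a read qualifies only if one
segment covers both flanks (this is also what keeps reads from other repeat
units out of the local assembly). The built-in engine star-aligns the
windows against the median-length one (Biostrings global alignment,
match 2 / mismatch −4 / gap open 4 / extend 2 — minimap2-like scoring) and
takes the column majority, including majority-voted insertions; at ≤ 15
reads and ~1–3 kb windows this is fast and, at 2% read error and depth
≥ 10, reproduces the haplotype to ≥ 99.9% identity. An external assembler
can be plugged in via `engine=`. The consensus must still match the contig
on both flanks (≥ 75% identity over 200 bp) or the correction is abandoned
and the error retained — uncorrectable errors are reported, never silently
dropped.

For a haplotype switch only the better-supported side's reads are used
(ties pick the expansion side), reconstructing one haplotype instead of a
blend. Inversions are corrected directly by reverse-complementing the
called interval: the sequence content is already correct, and breakpoint
imprecision of a few bases leaves at most a handful of residual small-scale
errors. The read-collection flank (`flank = 5000` bp) exceeds the patch
window so switch-side classification has context to work with.

## 6. Reference-based mode

When a reference is supplied, contigs are aligned with the `asm5` preset
and the package reports NA50 (N50 over aligned block lengths, with the
half-total taken over the *full* assembly length so unaligned sequence
counts against it — the established convention for this statistic), contig
mapping rate, and genome coverage, plus a dotplot segment table. Error
coordinates are projected through the block CIGARs; only match columns have
an exact image, contig positions inside insertions inherit the nearest left
match and are flagged approximate, and errors in unaligned regions are
flagged unprojectable. Reference-mode discrepancies include real genetic
variants by construction, so this mode projects and summarises but never
calls errors from reference alignment.

## 7. The simulation benchmark

The simulator defines the package's study conditions (defaults of
`sim_config()`):

* 5-Mb random genome with 4 N-gaps (the assembly splits there into ~1-Mb
  contigs; fragments < 10 kb are dropped);
* 1,600 SNPs (3.2 × 10⁻⁴/bp) and 160 indel SVs (3.2 × 10⁻⁵/bp), 67%
  heterozygous, het alleles assigned to a random haplotype; SV sizes
  50 + geometric (mean ≈ 250 bp, capped at 2 kb), matching the
  short-dominated spectrum of real genomes;
* an assembly built from haplotype 1 with 16 spiked structural errors
  (7 expansions, 7 collapses, 1 haplotype switch, 1 inversion — a 10:1
  SV-to-error ratio, so the variant filter is genuinely stressed, with all
  four error classes exercised) and 950 small-scale errors (1.9 × 10⁻⁴/bp;
  50% substitutions, 25% 1-bp expansions, 25% 1-bp collapses);
* 50× reads per run, lengths Normal(15000, 3000) truncated at 1 kb, both
  strands, depth split evenly across haplotypes; per-base error 2%
  (HiFi-like; substitution-leaning 50/25/25) or 15% (CLR-like; indel-rich
  10/60/30, after the known insertion-dominated PacBio CLR profile).

A haplotype switch is spiked by replacing a heterozygous insertion SV
(≥ 100 bp, carried by haplotype 1) with only its first half, so reads from
either haplotype disagree with the contig by ≥ 50 bp in opposite
directions — the detectable form of the event. Spiking the opposite
haplotype's allele instead would leave one haplotype in full agreement and
produce a 50%-support signal indistinguishable from the heterozygous
variant it sits on; such events are invisible to any read-support method
and are therefore not part of the truth set.

Structural loci keep ≥ 2 kb spacing from each other and from SV loci, and
all spikes stay ≥ 20 kb from contig ends and gaps; small errors keep
≥ 10 bp from variants. These spacings make the truth set unambiguous —
each call can be attributed to exactly one spiked event — at the cost of
not testing colliding events, which the clustering window could not
separate at any parameter setting. Every generator is a pure function of
`(config, seed)`; regenerating with the same seed is byte-identical.

Scoring matches calls to truth one-to-one, nearest first, within 500 bp and
reciprocal size 0.5 for structural events (the size test is waived for
haplotype switches, which legitimately match either side's signal).
Small-scale matches require the same kind within ± 5 bp: aligner left-
normalisation inside homopolymers shifts 1-bp indel coordinates by a few
bases, and exact-position matching would count such pairs as both a false
positive and a false negative.

### What the simulator does not emulate

Errors are i.i.d. per base at a fixed rate. Real long reads have bursty,
quality-correlated errors, homopolymer-dependent indels, and chimeras;
PBSIM-style quality models produce them, this simulator intentionally does
not. Consequences observed in the package's own benchmark: with HiFi-like
reads results track the published behaviour closely (structural
recall/precision near 100%, small-scale F1 > 99%), but with CLR-like reads
the small-scale recall sits around 92–96% across seeds instead of the ~86%
reported for quality-model CLR reads — uniform noise preserves more
per-column signal than bursty noise at the same mean accuracy. Passing benchmarks here
demonstrate the correctness of the detection and filtering logic, not
performance on real flowcell artifacts. The repeat structure of real
genomes (the main source of assembly errors in practice) is also absent:
a random genome has no long repeats, so the adaptive clustering window and
the repeat-unit read collection are exercised by the unit tests, not
stressed by the benchmark.

### Problem sizes

The benchmark suite runs three seeds × two read chemistries at the 5-Mb /
50× scale (about 250 Mb of reads per run, 1.5–4 minutes each on one CPU,
dominated by minimap2), which gives ~100 structural and ~5,700 small-scale
truth events per chemistry — enough to resolve the recall/precision levels
being checked while staying desk-scale. Oracle-equivalence checks
(binomial tail vs exhaustive enumeration, N50 vs brute-force cumulation,
depth vs per-position counting) run at small n where the oracles are exact
by construction.

## 8. Numerical and degenerate-input choices

* Binomial tails use `pbinom(..., lower.tail = FALSE)` — exact and stable
  to n = 10,000; no normal approximation anywhere.
* N50 uses the inclusive tie rule (cumulative sum *equal* to half the
  total qualifies), so `[5, 5]` has N50 5.
* Ambiguous (`N`) bases count toward contig length: contigs are evaluated
  as emitted.
* Zero reads, zero contigs after filtering, empty alignment files, and
  empty error lists all return well-formed zero-filled results with a
  warning where the statistic is undefined (mapping rate of zero reads),
  and `NaN` precision for an empty call set.
* Cluster positions and sizes are medians of member signals — robust to
  the odd mis-anchored read.
* All internal coordinates are 0-based half-open; conversion happens only
  in writers (BED output is 0-based half-open by format definition, SAM
  input converts on parse).
* Evaluation keeps every contig by default (`min_len = 0`); excluding short
  contigs is an explicit choice the caller makes, not a silent default.
* Mean alignment depth is total aligned contig-span bases over total contig
  bases — a deterministic function of the alignments, unlike read-length
  based definitions that depend on clipping conventions.

## 9. Known limitations

* Genotype-aware evaluation stops at the haplotype-switch class; phasing
  is out of scope, and ploidy > 2 violates the 50%/100% support dichotomy
  the filters are built on.
* PAF input (without sequences) supports structural detection only;
  small-scale calling needs SAM/BAM with sequences.
* The built-in consensus engine assumes the patch window fits in single
  read spans; errors larger than the read length minus two anchors are
  reported but uncorrectable without an external engine.
* Sensitivity degrades below ~10× effective coverage (half that per
  haplotype at heterozygous loci); columns under 5 spanning reads are
  uncallable by design.
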