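---
title: "Quantifying RNAPII promoter-proximal pausing with stallr"
author: "stallr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNAPII promoter-proximal pausing with stallr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stallr)
library(GenomicRanges)
```

## The statistic

RNA polymerase II frequently pauses 20–60 bp downstream of the
transcription start site before committing to productive elongation. In
RNAPII ChIP-seq this appears as a sharp read peak at the promoter and a
lower, broader signal along the transcribed region. stallr summarises the
balance per transcript as the stalling index

$$\mathrm{SI} = \frac{\mathrm{TSS}}{\mathrm{GB}},$$

the ratio of read counts in two windows defined in transcript
orientation with closed endpoints:

* **TSS window** — $[\mathrm{tss} - 300, \mathrm{tss} + 300]$,
  width $601$ bp;
* **gene-body window** — $[\mathrm{tss} + 300, \mathrm{TES} + 3000]$,
  genomic width $L - 300 + 3000$ bp for a transcript of genomic span
  $L$.

A high SI indicates promoter-proximal accumulation ("stalling" or
"pausing"); a low SI indicates efficient release into the gene body. The
reciprocal, the travelling ratio $\mathrm{TR} = \mathrm{GB}/\mathrm{TSS}$,
is used with both orientations in the literature, so stallr emits both
columns, labelled, and leaves the choice of convention to the analyst.
Where both are defined and non-zero they satisfy
$\mathrm{SI}\cdot\mathrm{TR} = 1$ to floating-point accuracy.

Two filters precede the ratio:

1. **length filter** — only transcripts whose genomic span is *strictly*
   above 600 bp are quantified ("above" is read as a strict inequality: a
   600 bp transcript fails, a 601 bp one passes). This also guarantees
   the gene-body window is non-empty, since its in-transcript start sits
   300 bp past the TSS.
2. **peak filter** — the transcript must carry an RNAPII peak overlapping
   its TSS window by at least one base. Requiring peak evidence removes
   unexpressed transcripts whose SI would be noise over noise.

Transcripts failing either filter stay in the output with
`passed_length` / `passed_peak` flags and `NA` ratios, keeping the filter
cascade auditable.

## Conventions and boundary decisions

**Coordinates.** All regions are `GRanges`, 1-based with closed
endpoints — the native Bioconductor convention. BED-family inputs
(BED, BED12, narrowPeak), which are 0-based half-open on disk, are
converted on import by `rtracklayer`; GTF coordinates are used as-is.
Tests pin the conversions explicitly.

**The shared base.** The printed window definitions share the single
coordinate $\mathrm{tss}+300$, so by default a read overlapping only
that base counts in *both* windows. This is preserved literally;
`disjoint = TRUE` starts the gene body one base later for strict
partition semantics. At realistic read depths the effect on SI is
negligible, but the policy is explicit and tested.

**Transcript length.** "Length" is genomic span (`end − start + 1`), not
spliced mature length: the SI operates on genomic read counts over
genomic windows, and exon structure plays no role in the definition.
For genes with several isoforms the SI is computed per transcript; no
isoform collapsing is attempted.

**Strand.** The TSS is the interval start on `+` and the interval end on
`-`; minus-strand windows are mirrored in genomic coordinates (gene body
$[\mathrm{TES} - 3000, \mathrm{tss} - 300]$). Reads are counted
regardless of their own strand — RNAPII ChIP-seq fragments carry no
strand information about the transcript. Unstranded transcript records
are rejected at parse time since their TSS is undefined.

**Windows off the chromosome end** are clamped to `[1, chrom_length]`
rather than dropped, preserving transcripts near contig edges; a window
falling entirely off the sequence is an error.

**Counting modes.** `overlap` counts a read if its aligned span shares at
least one base with the window — the common convention for ChIP-seq
interval counting and the default. `five_prime` counts a read if its
5′-most aligned base falls inside the window; this mode makes the
simulator's SI expectation exact (below) and is less sensitive to read
length at window boundaries. Since a 5′ end inside implies overlap, the
`overlap` count always dominates the `five_prime` count. Secondary and
supplementary alignments are always excluded; duplicates are kept unless
`dedup = TRUE`. No library-size normalisation is applied anywhere: the SI
is a within-sample ratio and is invariant under scaling of all counts.

**Raw counts vs densities.** The SI is defined here as a ratio of raw
read *counts*. Because the two windows differ in width, a
density-oriented reading is also defensible, so
`normalize_by_width = TRUE` switches to
$(\mathrm{TSS}/601)\,/\,(\mathrm{GB}/w_{GB})$. The raw-count form is the
default; the option makes the ambiguity explicit instead of silently
choosing.

**Zero denominators.** `GB = 0` yields an undefined SI (`NA`), not
infinity: undefined is honest, and distribution summaries simply exclude
those transcripts. A pseudocount added to both counts is available but
opt-in, because it changes rankings.

## Peak processing

Peak significance is carried as $-\log_{10}(p)$, matching the narrowPeak
pValue column; plain BED peaks default to 0 with a warning. The upstream
peak-calling procedure is out of scope — stallr consumes peak calls. Two
knobs that the analysis requires but that have no single canonical
value are exposed as mandatory-with-default configuration:

* **significance threshold** — default raw $p \le 10^{-5}$
  ($-\log_{10} p \ge 5$), a conventional ChIP-seq cutoff;
* **replicate pooling** — `union` (default): merge all replicates'
  peaks into disjoint regions; or `support_k`: keep the maximal regions
  covered by peaks from at least $k$ distinct replicates. `support_k`
  with $k = 1$ is identical to union, a property-tested identity. Pooled
  regions carry the maximum $-\log_{10}(p)$ over contributing peaks.

## The synthetic-data generator

The generator exists so that every stage — windows, counting, peaks,
pooling, SI — can be validated against known ground truth without any
external data. It emulates exactly the statistical structure the SI
quantifies, and nothing else:

* transcripts are placed on one synthetic chromosome with non-overlapping
  windows, lengths uniform in 1–5 kb, strands drawn fairly;
* each read lands in its transcript's TSS window with probability
  $p$ (`pause_fraction`) and in the gene-body window otherwise, 5′
  position uniform within the window, read length fixed at 50 bp, all
  mapq 60;
* a configurable fraction of transcripts receives a peak covering its
  TSS window in every replicate, plus replicate-private decoy peaks away
  from all TSS windows.

Under 5′-end counting the TSS count per transcript is
$X \sim \mathrm{Binomial}(n, p)$ and
$\mathrm{SI} = X/(n - X)$, so the median SI converges on
$p/(1-p)$. With the default validation cohort — 200 transcripts at
10,000 reads each — the median SI recovers $p/(1-p)$ within a few
percent at $p = 0.8$ (expectation 4) and $p = 0.5$ (expectation 1),
and the recovery holds separately on each strand, which exercises the
window strand-flip logic. These sizes keep the full recovery run in
seconds while leaving the binomial standard error far below the
tolerance asserted.

What the generator deliberately does **not** model: sequencing error,
GC and mappability bias, fragment-size effects, peak-call noise at the
TSS, or a mechanistic elongation profile along the gene body. Passing
recovery tests therefore demonstrate that the *computation* is correct —
windows, strand handling, counting, filters, ratios — not that the SI is
robust to the biases of real ChIP-seq libraries; on real data the usual
quality control upstream of this package still applies.

Reads are assigned to windows rather than walked along the gene because
an analytic acceptance surface ($p/(1-p)$, binomial bounds) is worth
more for validation than mechanistic realism that nothing could be
checked against.

## The sample-sheet model

Multi-assay studies ship an inventory table linking each sequencing
sample to its replicates and its input/baseline samples. stallr models
such sheets directly: replicate fields `i/n` are split and
cross-validated (rows sharing a name stem and declaring $n > 1$ must
observe indices $1..n$ exactly; rows declaring `1/1` are independent
samples, e.g. distinct tumour animals, and are validated individually),
dash-ranged baseline references like `GSM1234734-7` expand by
trailing-digit replacement, and organism codes map to genome builds
(mmu → mm9, hsa → hg18). The packaged 94-sample fixture is transcribed
verbatim from the study it mirrors, including its typographic null
markers and two input rows that nonetheless list a ChIP target — those
are surfaced as WARNING-level issues, not errors, because the validator's
job is to describe the sheet, not to rewrite it. Greek characters in
model names (Eμ-myc) get an ASCII alias for querying, with the original
preserved.

## Numerical and degenerate-input behaviour

* `si * tr = 1` is exact to $10^{-12}$ wherever both are defined and
  non-zero (it is the same division twice; the tolerance absorbs only
  rounding of the reciprocal).
* Empty inputs degrade gracefully: empty annotation → empty table; empty
  peak list → all `passed_peak = FALSE`, zero SIs; all-undefined SI →
  empty distribution summary with a warning.
* Counting is invariant under permutation of the read file, and unknown
  chromosomes in windows yield zero counts with a warning rather than an
  error, so partial annotations do not abort a run.
* All simulator functions are deterministic given the config seed, and
  each stage salts the seed independently, so regenerating reads does not
  perturb the annotation.

## Problem sizes used in the test suite

The suite validates counting against an all-pairs brute-force oracle on
randomized instances up to 1,000 × 1,000 intervals, pooling against a
per-base occupancy oracle on small chromosomes, and parameter recovery on
the 200-transcript, 10,000-read cohort at two pausing fractions. The
complete suite runs in under a minute on one CPU; the acceptance script
in about fifteen seconds.

## Known limitations

* No differential-stalling statistics between conditions; the package
  quantifies, comparison is left to downstream tools.
* No fragment-model corrections (extension/shift, paired-end
  reconstruction): reads are counted as aligned spans.
* The peak-at-TSS filter is binary; peak strength at the TSS is not
  propagated into the SI.
* BED12 input uses the record's full span; block (exon) structure is
  ignored by design, consistent with the genomic-span length definition.
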