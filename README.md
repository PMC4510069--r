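# stallr

Quantification of RNA polymerase II (RNAPII) promoter-proximal pausing
from ChIP-seq data.

In many cell types a large fraction of RNAPII accumulates just downstream
of the transcription start site (TSS) before being released into
productive elongation. The balance between promoter loading and gene-body
travel is commonly summarised per transcript by the **stalling index**

```
SI = TSS / GB
```

where `TSS` is the number of RNAPII ChIP-seq reads in the window
`[tss − 300 bp, tss + 300 bp]` and `GB` the number of reads in the gene
body `[tss + 300 bp, TES + 3000 bp]` (TES = transcription end site; both
intervals closed, so they deliberately share the single base at
`tss + 300`). The reciprocal convention, the **travelling ratio**
`TR = GB / TSS`, is also used in the literature; stallr reports both,
labelled. The SI is computed for every transcript whose genomic span is
strictly above 600 bp and whose TSS window carries an RNAPII peak;
transcripts failing either filter are reported with flags rather than
dropped.

Around that statistic the package provides the full working environment:

* strand-aware TSS / gene-body window derivation from GTF or BED12
  annotation (windows for minus-strand transcripts are mirrored in
  genomic coordinates);
* read counting over windows from indexed BAM files or in-memory
  alignments, in `overlap` (≥ 1 shared base) or `five_prime` (5′ end in
  window) mode;
* peak processing: narrowPeak/BED readers, significance filtering on
  −log10(p), and replicate pooling by union or by k-of-n replicate
  support;
* a validated multi-assay sample-sheet model (replicate bookkeeping,
  ranged input/baseline references such as `GSM1234734-7`), with a
  packaged 94-sample inventory as a worked fixture;
* a synthetic-data generator producing annotations, reads with a known
  pausing fraction, and replicate peak sets, so the entire pipeline is
  testable with no external data;
* a command line (`inst/exec/stallr`) with `stalling`, `pool-peaks`,
  `validate-sheet` and `simulate` subcommands.

Regions are plain `GRanges` throughout, so results drop directly into
any Bioconductor workflow.

## Worked example

Simulate a small cohort with a known pausing fraction of 0.8, pool the
replicate peak calls, and compute the stalling table:

```r
library(stallr)

cfg <- simulation_config(n_transcripts = 20, reads_per_transcript = 500,
                         pause_fraction = 0.8, seed = 7)
tx     <- simulate_annotation(cfg)
reads  <- simulate_rnapii_reads(tx, cfg)
pooled <- pool_replicates(simulate_peak_replicates(tx, cfg)$replicates,
                          mode = "union")
tab <- compute_stalling_table(reads, tx, pooled, mode = "five_prime")
print(tab, n = 3)
```

```
Stalling table: 20 transcripts
  windows: TSS +/-300 bp; GB [tss+300, TES+3000]; length > 600 bp; mode five_prime
  20 passed length filter, 20 have a TSS peak, 20 with SI
  median SI = 3.902, median TR = 0.2563
  transcript_id tss_count gb_count tss_width gb_width       si        tr
1        tx0001       402       99       601     4850 4.060606 0.2462687
2        tx0002       414       86       601     5597 4.813953 0.2077295
3        tx0003       410       91       601     6242 4.505495 0.2219512
```

Each read lands in the TSS window with probability 0.8, so TSS counts
hover around 0.8 × 500 = 400 and the SI around 0.8/0.2 = 4; the observed
median of 3.902 recovers that expectation from the full pipeline. The
per-transcript ratios satisfy `si × tr = 1` exactly.

`summary(tab)` prints 5/25/50/75/95% quantiles of the TSS counts,
gene-body counts and SI over transcripts with a defined SI, and
`plot(tab)` draws the three distributions side by side — the SI balances
promoter loading against gene-body travel, and the two count
distributions show which side moves.

The same run from the shell:

```sh
stallr simulate --outdir sim --n-transcripts 20 --reads 500 --seed 7
stallr stalling --bam sim/reads.bam --annotation sim/annotation.gtf \
       --peaks sim/peaks_rep1.narrowPeak,sim/peaks_rep2.narrowPeak,sim/peaks_rep3.narrowPeak \
       --mode five_prime --out table.tsv
```

## Sample-sheet utilities

```r
sheet <- read_sample_sheet(stallr_example_sheet())
nrow(sheet)                       # 94
validate_sheet(sheet)             # cross-checks replicate sets and baselines
query_samples(sheet, model = "P493", data_type = "ChIP-Seq", target = "Myc")
```

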