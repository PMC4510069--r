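# Independent brute-force oracles and tiny fixture builders used across
# the suite. The oracles operate on plain data.frames so they share no
# code path with the package's GRanges-backed engine.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# all-pairs overlap scan: data.frames with chrom/start/end (1-based closed)
brute_count_overlaps <- function(q, s) {
  vapply(seq_len(nrow(q)), function(i) {
    sum(s$chrom == q$chrom[i] & s$start <= q$end[i] & s$end >= q$start[i])
  }, 1L)
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr), stringsAsFactors = FALSE)
}

# per-base occupancy over a small chromosome: returns integer vector of
# per-position coverage counts (position i = base i, 1-based)
base_occupancy <- function(df, chrom_len) {
  occ <- integer(chrom_len)
  for (i in seq_len(nrow(df))) {
    idx <- df$start[i]:df$end[i]
    idx <- idx[idx >= 1 & idx <= chrom_len]
    occ[idx] <- occ[idx] + 1L
  }
  occ
}

random_intervals <- function(n, chrom_len = 10000L,
                             chroms = c("chr1", "chr2"),
                             max_width = 200L) {
  s <- sample.int(chrom_len - max_width, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  GRanges(sample(chroms, n, replace = TRUE), IRanges(s, width = w))
}

# one stranded transcript as a GRanges with a transcript_id
make_tx <- function(chrom, start, end, strand, id = "tx1") {
  tx <- GRanges(chrom, IRanges(start, end), strand = strand)
  tx$transcript_id <- id
  tx$gene_id <- paste0("g_", id)
  tx
}

# reads GRanges with seqlengths, for BAM round trips
make_reads <- function(chrom, starts, width = 50L, strand = "+",
                       chrom_len = 100000L) {
  r <- GRanges(chrom, IRanges(as.integer(starts), width = width),
               strand = strand,
               seqinfo = GenomeInfoDb::Seqinfo(chrom, chrom_len))
  r$mapq <- 60L
  r
}
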