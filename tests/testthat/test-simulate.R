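test_that("annotation generation is deterministic, fair and non-overlapping", {
  cfg <- simulation_config(n_transcripts = 40, seed = 1)
  tx1 <- simulate_annotation(cfg)
  tx2 <- simulate_annotation(cfg)
  expect_identical(as.data.frame(tx1), as.data.frame(tx2))
  expect_length(tx1, 40)
  expect_true(all(width(tx1) >= cfg$length_range[1] &
                    width(tx1) <= cfg$length_range[2]))
  # both strands represented (drawn fairly)
  st <- table(as.character(strand(tx1)))
  expect_true(all(c("+", "-") %in% names(st)))
  # no two gene-body windows overlap, even ignoring strand
  gb <- genebody_window(tx1)
  expect_true(all(countOverlaps(gb, gb, ignore.strand = TRUE) == 1L))
  # empty config
  expect_length(simulate_annotation(simulation_config(n_transcripts = 0)), 0)
  # impossible placement is refused with advice
  expect_error(
    simulate_annotation(simulation_config(n_transcripts = 40,
                                          chrom_length = 10000L)),
    "chrom_length")
})

test_that("read simulation hits the TSS window at the configured fraction", {
  # degenerate fractions
  for (p in c(0, 1)) {
    cfg <- simulation_config(n_transcripts = 10, reads_per_transcript = 200,
                             pause_fraction = p, seed = 3)
    tx <- simulate_annotation(cfg)
    reads <- simulate_rnapii_reads(tx, cfg)
    in_tss <- count_reads_in_window(reads, tss_window(tx),
                                    mode = "five_prime")
    if (p == 1) expect_equal(sum(in_tss), length(reads))
    else expect_equal(sum(in_tss), 0L)
  }
  # binomial bounds at p = 0.8: each transcript within 4 sd of n*p
  cfg <- simulation_config(n_transcripts = 10,
                           reads_per_transcript = 10000, seed = 4)
  tx <- simulate_annotation(cfg)
  reads <- simulate_rnapii_reads(tx, cfg)
  tss_counts <- count_reads_in_window(reads, tss_window(tx),
                                      mode = "five_prime")
  bound <- 4 * sqrt(10000 * 0.8 * 0.2)
  # the shared boundary base can add a handful of gene-body reads
  expect_true(all(abs(tss_counts - 8000) <= bound + 10))
  # determinism
  reads2 <- simulate_rnapii_reads(tx, cfg)
  expect_identical(start(reads), start(reads2))
})

test_that("peak replicate simulation controls TSS coverage and decoys", {
  cfg <- simulation_config(n_transcripts = 15, reads_per_transcript = 10,
                           peak_fraction = 1, n_replicates = 3, seed = 5)
  tx <- simulate_annotation(cfg)
  pk <- simulate_peak_replicates(tx, cfg)
  for (r in pk$replicates)
    expect_true(all(has_peak_at_tss(tx, r)))
  expect_true(all(pk$truth$has_peak))

  # support_k with k = n_replicates removes the replicate-private decoys
  pooled <- pool_replicates(pk$replicates, mode = "support_k",
                            k = cfg$n_replicates)
  tssw <- tss_window(tx)
  expect_true(all(count_overlapping(pooled, tssw) > 0))

  cfg0 <- simulation_config(n_transcripts = 15, reads_per_transcript = 10,
                            peak_fraction = 0, seed = 6)
  tx0 <- simulate_annotation(cfg0)
  pk0 <- simulate_peak_replicates(tx0, cfg0)
  reads0 <- simulate_rnapii_reads(tx0, cfg0)
  pooled0 <- pool_replicates(pk0$replicates, mode = "union")
  tab0 <- compute_stalling_table(reads0, tx0, pooled0)
  expect_equal(sum(!is.na(tab0$si)), 0)
})

test_that("simulator files round-trip through the package readers", {
  cfg <- simulation_config(n_transcripts = 12, reads_per_transcript = 100,
                           seed = 7)
  dir <- tempfile()
  dir.create(dir)
  tx <- simulate_annotation(cfg, gtf = file.path(dir, "ann.gtf"))
  reads <- simulate_rnapii_reads(tx, cfg, bam = file.path(dir, "reads"))
  pk <- simulate_peak_replicates(tx, cfg, dir = dir)

  tx_back <- read_transcripts(file.path(dir, "ann.gtf"))
  expect_equal(start(tx_back), start(tx))
  expect_equal(as.character(strand(tx_back)), as.character(strand(tx)))
  expect_equal(tx_back$transcript_id, tx$transcript_id)

  bam_reads <- read_alignments(file.path(dir, "reads.bam"))
  expect_equal(length(bam_reads), length(reads))

  rep1 <- read_peaks(file.path(dir, "peaks_rep1.narrowPeak"))
  expect_equal(length(rep1), length(pk$replicates[[1]]))
  expect_equal(sort(start(rep1)), sort(start(pk$replicates[[1]])))

  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(truth), 12)
  expect_equal(truth$pause_fraction, rep(cfg$pause_fraction, 12))
})

test_that("pause-fraction recovery holds separately on each strand", {
  cfg <- simulation_config(n_transcripts = 60, reads_per_transcript = 2000,
                           pause_fraction = 0.6, seed = 8)
  tx <- simulate_annotation(cfg)
  reads <- simulate_rnapii_reads(tx, cfg)
  pk <- simulate_peak_replicates(tx, cfg)
  pooled <- pool_replicates(pk$replicates, mode = "union")
  tab <- compute_stalling_table(reads, tx, pooled, mode = "five_prime")
  expected <- 0.6 / 0.4
  for (s in c("+", "-")) {
    ids <- tx$transcript_id[as.character(strand(tx)) == s]
    med <- median(tab$si[tab$transcript_id %in% ids], na.rm = TRUE)
    expect_lt(abs(med - expected) / expected, 0.10)
  }
})
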