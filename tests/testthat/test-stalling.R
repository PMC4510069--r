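test_that("SI and TR are the two ratio conventions with NA where undefined", {
  expect_equal(stalling_index(100, 50), 2)
  expect_equal(stalling_index(0, 50), 0)
  expect_true(is.na(stalling_index(10, 0)))
  expect_equal(travelling_ratio(100, 50), 0.5)
  expect_true(is.na(travelling_ratio(0, 50)))
  # reciprocal identity on the worked pair
  expect_equal(stalling_index(100, 50) * travelling_ratio(100, 50), 1)
  # density-normalised variant
  expect_equal(stalling_index(100, 50, normalize_by_width = TRUE,
                              tss_width = 601, gb_width = 4700),
               (100 / 601) / (50 / 4700))
  expect_error(stalling_index(100, 50, normalize_by_width = TRUE),
               "requires")
  # pseudocount rescues the undefined case
  expect_equal(stalling_index(10, 0, pseudocount = 1), 11)
})

test_that("SI is scale-invariant and monotone in the TSS count", {
  set.seed(41)
  tss <- sample(1:500, 50)
  gb <- sample(1:500, 50)
  for (k in c(2L, 7L, 100L))
    expect_equal(stalling_index(k * tss, k * gb), stalling_index(tss, gb))
  si <- stalling_index(1:100, rep(37, 100))
  expect_true(all(diff(si) > 0))
})

test_that("filter cascade: only long transcripts with a TSS peak receive an SI", {
  # 4 transcripts, lengths 500/601/2000/2000; peaks on the TSS of the
  # 601 bp one and one 2 kb one
  tx <- c(make_tx("chr1", 10001, 10500, "+", "short"),
          make_tx("chr1", 30001, 30601, "+", "len601"),
          make_tx("chr1", 50001, 52000, "+", "long_nopeak"),
          make_tx("chr1", 70001, 72000, "-", "long_peak"))
  peaks <- c(gi("chr1", 29901, 30101), gi("chr1", 71901, 72100))
  peaks$neg_log10_p <- c(9, 9)
  set.seed(5)
  reads <- make_reads("chr1", sample(9000:75000, 2000, replace = TRUE),
                      width = 50, chrom_len = 100000L)
  tab <- compute_stalling_table(reads, tx, peaks)
  expect_s3_class(tab, "stalling_table")
  expect_equal(nrow(tab), 4)
  expect_equal(sum(!is.na(tab$si)), 2)
  expect_equal(tab$transcript_id[!is.na(tab$si)],
               sort(c("len601", "long_peak")))
  # rows are sorted by id: len601, long_nopeak, long_peak, short
  expect_equal(tab$passed_length, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(tab$passed_peak, c(TRUE, FALSE, TRUE, FALSE))
  # empty peak list: no SI anywhere
  tab0 <- compute_stalling_table(reads, tx, peaks[0])
  expect_equal(sum(!is.na(tab0$si)), 0)
  expect_false(any(tab0$passed_peak))
})

test_that("hand-placed reads yield hand-computed SI values", {
  # 5 transcripts with deliberate counts; all peaked, all > 600 bp
  tx <- do.call(c, lapply(1:5, function(i)
    make_tx("chr1", 20000L * i + 1L, 20000L * i + 2000L, "+",
            sprintf("t%d", i))))
  peaks <- tss_window(tx)
  peaks$neg_log10_p <- rep(10, 5)
  # per transcript i: i reads in the TSS window, 2i in the gene body
  place <- function(i) {
    tss_s <- 20000L * i + 1L - 250L
    gb_s <- 20000L * i + 1000L
    c(seq(tss_s, by = 60L, length.out = i),
      seq(gb_s, by = 60L, length.out = 2L * i))
  }
  reads <- make_reads("chr1", unlist(lapply(1:5, place)), width = 50,
                      chrom_len = 200000L)
  tab <- compute_stalling_table(reads, tx, peaks)
  expect_equal(tab$tss_count, 1:5)
  expect_equal(tab$gb_count, 2L * (1:5))
  expect_equal(tab$si, rep(0.5, 5))
  expect_equal(tab$tr, rep(2, 5))
})

test_that("reciprocal identity holds wherever both ratios are defined", {
  cfg <- simulation_config(n_transcripts = 60, reads_per_transcript = 200,
                           pause_fraction = 0.5, seed = 42)
  tx <- simulate_annotation(cfg)
  reads <- simulate_rnapii_reads(tx, cfg)
  pk <- simulate_peak_replicates(tx, cfg)
  pooled <- pool_replicates(pk$replicates, mode = "union")
  tab <- compute_stalling_table(reads, tx, pooled, mode = "five_prime")
  ok <- !is.na(tab$si) & !is.na(tab$tr) & tab$si > 0 & tab$tr > 0
  expect_gt(sum(ok), 0)
  expect_true(all(abs(tab$si[ok] * tab$tr[ok] - 1) < 1e-12))
  # no transcript failing a filter carries a defined SI
  expect_false(any(!is.na(tab$si) & !(tab$passed_length & tab$passed_peak)))
})

test_that("distribution summary reports quantiles over defined SIs only", {
  df <- data.frame(tss_count = c(10, 20, 30, 5), gb_count = c(10, 10, 10, 0),
                   si = c(1, 2, 3, NA))
  s <- si_distribution_summary(df)
  expect_equal(s$n_defined, 3L)
  expect_equal(unname(s$quantiles["si", "q50"]), 2)
  expect_equal(colnames(s$quantiles), c("q5", "q25", "q50", "q75", "q95"))
  # single defined SI: all quantiles collapse onto it
  one <- si_distribution_summary(
    data.frame(tss_count = 7, gb_count = 7, si = 1.7))
  expect_true(all(one$quantiles["si", ] == 1.7))
  # all-undefined input warns and returns an empty summary
  expect_warning(
    none <- si_distribution_summary(
      data.frame(tss_count = 1, gb_count = 0, si = NA_real_)),
    "no transcripts")
  expect_equal(none$n_defined, 0L)
  # histogram bins are log10-spaced
  expect_equal(diff(log10(s$si_histogram$breaks)),
               rep(diff(log10(s$si_histogram$breaks))[1],
                   length(s$si_histogram$breaks) - 1L))
  expect_equal(sum(s$si_histogram$counts), 3L)
})

test_that("stalling table prints, summarises, plots and serialises", {
  df <- data.frame(tss_count = c(10, 20), gb_count = c(10, 5),
                   si = c(1, 4))
  tx <- c(make_tx("chr1", 1001, 3000, "+", "a"),
          make_tx("chr1", 5001, 7000, "+", "b"))
  peaks <- tss_window(tx)
  peaks$neg_log10_p <- c(8, 8)
  reads <- make_reads("chr1", sample(500:8000, 500, replace = TRUE),
                      width = 50, chrom_len = 20000L)
  tab <- compute_stalling_table(reads, tx, peaks)
  expect_output(print(tab), "Stalling table: 2 transcripts")
  expect_s3_class(summary(tab), "si_summary")
  f <- tempfile(fileext = ".png")
  png(f); plot(tab); dev.off()
  expect_true(file.size(f) > 0)
  tsv <- tempfile(fileext = ".tsv")
  write_stalling_tsv(tab, tsv, header_comments = "run")
  back <- read.table(tsv, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(back$transcript_id, tab$transcript_id)
  expect_equal(back$si, tab$si)
})
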