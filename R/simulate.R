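## Synthetic-data generator: toy annotations, RNAPII reads with a known
## promoter-pausing fraction, and replicate peak sets.
##
## The generator assigns each read to the TSS window with probability
## `pause_fraction` and to the gene-body window otherwise, with the 5' end
## uniform inside the chosen window. It is deliberately not a mechanistic
## elongation model: under 5'-end counting the TSS count per transcript is
## Binomial(reads_per_transcript, pause_fraction), so the stalling index
## has the analytic expectation p/(1-p) and recovery can be tested exactly.
## Reads are single-end, fixed length, mapq 60.

#' Simulation configuration
#'
#' Defaults encode the cohort used throughout the package's validation:
#' 200 transcripts of 1-5 kb on a single synthetic chromosome, 10,000
#' reads per transcript, pausing fraction 0.8 (strongly stalled; the
#' analytic median SI is p/(1-p) = 4), every transcript carrying a TSS
#' peak in each of 3 replicates plus 20 replicate-private decoy peaks.
#'
#' @param n_transcripts number of transcripts.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp; `NULL` sizes it to fit all
#'   transcripts with non-overlapping windows.
#' @param length_range min/max transcript genomic span (bp); keep the
#'   minimum above 600 unless deliberately testing the length filter.
#' @param pause_fraction probability a read falls in the TSS window.
#' @param reads_per_transcript reads simulated per transcript.
#' @param read_length aligned span of each read (bp).
#' @param peak_fraction fraction of transcripts given a TSS peak.
#' @param n_replicates number of peak replicates.
#' @param decoys_per_replicate replicate-private decoy peaks away from all
#'   TSS windows.
#' @param flank,gb_offset,gb_tail window geometry (bp), matching the
#'   quantification defaults.
#' @param seed integer seed; every generator call is deterministic given
#'   the config.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_transcripts = 200L, chrom = "chrS",
                              chrom_length = NULL,
                              length_range = c(1000L, 5000L),
                              pause_fraction = 0.8,
                              reads_per_transcript = 10000L,
                              read_length = 50L, peak_fraction = 1,
                              n_replicates = 3L,
                              decoys_per_replicate = 20L,
                              flank = 300L, gb_offset = 300L,
                              gb_tail = 3000L, seed = 1L) {
  stopifnot(pause_fraction >= 0, pause_fraction <= 1,
            peak_fraction >= 0, peak_fraction <= 1,
            length_range[1] >= 1L, length_range[2] >= length_range[1],
            n_transcripts >= 0L, reads_per_transcript >= 1L,
            read_length >= 1L, n_replicates >= 1L)
  structure(as.list(environment()), class = "sim_config")
}

## run code under a derived seed without clobbering the caller's RNG state
with_sim_seed <- function(seed, salt, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + salt) %% .Machine$integer.max)
  force(code)
}

## footprint of a transcript's windows on either strand: 3300 bp + flank
## beyond each transcript end covers TSS window and gene-body tail
sim_margin <- function(config) config$gb_tail + config$gb_offset +
  config$flank + config$read_length + 10L

#' Simulate a toy transcript annotation
#'
#' Places `n_transcripts` non-overlapping transcripts (windows included)
#' on one chromosome, with lengths uniform in `length_range` and strands
#' drawn fairly, so roughly half are on each strand. Deterministic given
#' the config seed.
#'
#' @param config a [simulation_config()].
#' @param gtf optional path; when given, the annotation is also written as
#'   GTF.
#' @return Stranded `GRanges` with `transcript_id` and `gene_id`, carrying
#'   the chromosome length in its `seqinfo`.
#' @export
simulate_annotation <- function(config, gtf = NULL) {
  n <- config$n_transcripts
  margin <- sim_margin(config)
  if (n == 0L) {
    out <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(
      config$chrom, config$chrom_length %||% 10000L))
    out$transcript_id <- character(0); out$gene_id <- character(0)
    return(out)
  }
  out <- with_sim_seed(config$seed, 101L, {
    len <- sample(seq(config$length_range[1], config$length_range[2]),
                  n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gap <- sample(50:200, n, replace = TRUE)
    slot <- len + 2L * margin + gap
    start <- margin + c(0L, cumsum(slot))[seq_len(n)] + margin
    end <- start + len - 1L
    needed <- start[n] + len[n] + margin + config$read_length
    chrom_len <- config$chrom_length %||% needed
    if (chrom_len < needed)
      stop("cannot place ", n, " transcripts on a ", chrom_len,
           " bp chromosome without window overlap; need >= ", needed,
           " bp (increase chrom_length)")
    gr <- GenomicRanges::GRanges(
      config$chrom, IRanges::IRanges(start, end), strand = strand,
      seqinfo = GenomeInfoDb::Seqinfo(config$chrom, chrom_len))
    gr$transcript_id <- sprintf("tx%04d", seq_len(n))
    gr$gene_id <- sprintf("gene%04d", seq_len(n))
    gr
  })
  if (!is.null(gtf)) write_gtf(out, gtf)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## minimal GTF writer for transcript records (1-based closed, as GTF is)
write_gtf <- function(tx, path) {
  lines <- sprintf(
    '%s\tstallr_sim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    as.character(GenomeInfoDb::seqnames(tx)), GenomicRanges::start(tx),
    GenomicRanges::end(tx), as.character(GenomicRanges::strand(tx)),
    tx$gene_id, tx$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate RNAPII ChIP-seq reads
#'
#' For every transcript, each of `reads_per_transcript` reads lands in the
#' TSS window with probability `pause_fraction` and in the gene-body
#' window otherwise; the 5' position is uniform within the chosen window
#' and the read strand is drawn fairly (counting ignores read strand; the
#' 5' anchor respects it). Deterministic given the config seed.
#'
#' @param tx annotation from [simulate_annotation()].
#' @param config the same [simulation_config()].
#' @param bam optional path prefix; when given, reads are also written as
#'   a coordinate-sorted, indexed BAM (`<bam>.bam` + `.bai`).
#' @return `GRanges` of aligned read spans with `mapq = 60` and a
#'   `transcript_id` column recording the source transcript.
#' @export
simulate_rnapii_reads <- function(tx, config, bam = NULL) {
  chrom_len <- GenomeInfoDb::seqlengths(tx)[config$chrom]
  reads <- with_sim_seed(config$seed, 202L, {
    tssw <- tss_window(tx, flank = config$flank)
    gbw <- genebody_window(tx, offset = config$gb_offset,
                           tail = config$gb_tail)
    n_r <- config$reads_per_transcript
    per_tx <- lapply(seq_along(tx), function(i) {
      in_tss <- stats::runif(n_r) < config$pause_fraction
      win_s <- ifelse(in_tss, GenomicRanges::start(tssw)[i],
                      GenomicRanges::start(gbw)[i])
      win_e <- ifelse(in_tss, GenomicRanges::end(tssw)[i],
                      GenomicRanges::end(gbw)[i])
      p5 <- win_s + floor(stats::runif(n_r) * (win_e - win_s + 1L))
      strand <- sample(c("+", "-"), n_r, replace = TRUE)
      s <- ifelse(strand == "+", p5, p5 - config$read_length + 1L)
      list(start = as.integer(s), strand = strand, tx = i)
    })
    s <- unlist(lapply(per_tx, `[[`, "start"), use.names = FALSE)
    strand <- unlist(lapply(per_tx, `[[`, "strand"), use.names = FALSE)
    txi <- rep(seq_along(tx), each = n_r)
    s <- pmax(1L, pmin(s, as.integer(chrom_len) - config$read_length + 1L))
    gr <- GenomicRanges::GRanges(
      config$chrom, IRanges::IRanges(s, width = config$read_length),
      strand = strand,
      seqinfo = GenomeInfoDb::Seqinfo(config$chrom,
                                      as.integer(chrom_len)))
    gr$mapq <- 60L
    gr$transcript_id <- tx$transcript_id[txi]
    gr
  })
  if (!is.null(bam)) write_reads_bam(reads, bam)
  reads
}

#' Write simulated reads as a sorted, indexed BAM
#'
#' Serialises aligned spans to SAM text (flag 0/16, CIGAR `<len>M`,
#' mapq from the `mapq` column) and converts with samtools via
#' [Rsamtools::asBam()].
#'
#' @param reads `GRanges` of aligned spans (e.g. from
#'   [simulate_rnapii_reads()]); needs `seqlengths` for the header.
#' @param prefix output path without the `.bam` extension.
#' @return Path to the indexed BAM file.
#' @export
write_reads_bam <- function(reads, prefix) {
  sl <- GenomeInfoDb::seqlengths(reads)
  if (anyNA(sl)) stop("reads need seqlengths to build a BAM header")
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sl), as.integer(sl)))
  mapq <- if (!is.null(reads$mapq)) as.integer(reads$mapq) else
    rep(60L, length(reads))
  flag <- ifelse(as.character(GenomicRanges::strand(reads)) == "-", 16L, 0L)
  body <- sprintf("read%07d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                  seq_along(reads), flag,
                  as.character(GenomeInfoDb::seqnames(reads)),
                  GenomicRanges::start(reads), mapq,
                  GenomicRanges::width(reads))
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, destination = prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

#' Simulate replicate peak sets
#'
#' A `peak_fraction` subset of transcripts receives a peak covering its
#' full TSS window in every replicate (significance `-log10(p)` uniform in
#' [6, 20]); each replicate additionally gets `decoys_per_replicate`
#' private decoy peaks placed away from all TSS windows (significance
#' uniform in [1, 8]). Deterministic given the config seed.
#'
#' @param tx annotation from [simulate_annotation()].
#' @param config the same [simulation_config()].
#' @param dir optional directory; when given, each replicate is written as
#'   `peaks_rep<i>.narrowPeak` and the truth table as `truth.tsv`
#'   (`transcript_id`, `pause_fraction`, `has_peak`).
#' @return List with `replicates` (list of peak `GRanges`) and `truth`
#'   (`data.frame`).
#' @export
simulate_peak_replicates <- function(tx, config, dir = NULL) {
  chrom_len <- as.integer(GenomeInfoDb::seqlengths(tx)[config$chrom])
  out <- with_sim_seed(config$seed, 303L, {
    n <- length(tx)
    n_peaked <- round(config$peak_fraction * n)
    peaked <- sort(sample(seq_len(n), n_peaked))
    tssw <- if (n > 0) tss_window(tx, flank = config$flank) else NULL
    decoy_w <- 400L
    reps <- lapply(seq_len(config$n_replicates), function(r) {
      true_gr <- if (n_peaked > 0) {
        g <- GenomicRanges::granges(tssw[peaked])
        GenomicRanges::strand(g) <- "*"
        g$score <- g$neg_log10_p <- stats::runif(n_peaked, 6, 20)
        g
      } else GenomicRanges::GRanges()
      # rejection-sample replicate-private decoys clear of all TSS windows
      decoys <- GenomicRanges::GRanges()
      tries <- 0L
      while (length(decoys) < config$decoys_per_replicate && tries < 200L) {
        need <- config$decoys_per_replicate - length(decoys)
        s <- sample.int(max(1L, chrom_len - decoy_w), need, replace = TRUE)
        cand <- GenomicRanges::GRanges(config$chrom,
                                       IRanges::IRanges(s, width = decoy_w))
        if (n > 0)
          cand <- cand[count_overlapping(cand, tssw) == 0L]
        decoys <- c(decoys, cand)
        tries <- tries + 1L
      }
      if (length(decoys) > 0) {
        decoys$score <- decoys$neg_log10_p <-
          stats::runif(length(decoys), 1, 8)
      } else {
        decoys$score <- decoys$neg_log10_p <- numeric(0)
      }
      p <- sort(c(true_gr, decoys))
      p$replicate_label <- sprintf("rep%d", r)
      p
    })
    truth <- data.frame(
      transcript_id = if (n > 0) tx$transcript_id else character(),
      pause_fraction = rep(config$pause_fraction, n),
      has_peak = seq_len(n) %in% peaked,
      stringsAsFactors = FALSE)
    list(replicates = reps, truth = truth)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (r in seq_along(out$replicates)) {
      p <- out$replicates[[r]]
      p$name <- sprintf("rep%d_peak%d", r, seq_along(p))
      write_narrowpeak(p, file.path(dir,
                                    sprintf("peaks_rep%d.narrowPeak", r)))
    }
    utils::write.table(out$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
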