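## Read counting over derived windows.
##
## Alignments come either from an indexed BAM (via GenomicAlignments) or
## from an in-memory GRanges of aligned spans. Two counting modes:
##   overlap    - a read counts if its aligned span shares >= 1 base with
##                the window (common interval-counting semantics);
##   five_prime - a read counts if its 5'-most aligned base (start on `+`,
##                end on `-`) lies inside the window. This mode makes the
##                simulator's stalling-index expectation exact.
## Secondary and supplementary alignments are always excluded; duplicates
## are kept unless dedup = TRUE.

#' Load aligned reads from a BAM file
#'
#' Primary alignments only (secondary, supplementary and unmapped records
#' are dropped). Returns aligned spans as a stranded `GRanges` with a
#' `mapq` metadata column.
#'
#' @param bam path to an indexed BAM file.
#' @param min_mapq minimum mapping quality (reads below are dropped).
#' @param dedup drop reads flagged as PCR/optical duplicates.
#' @return `GRanges` of aligned read spans.
#' @export
read_alignments <- function(bam, min_mapq = 0L, dedup = FALSE) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (dedup) FALSE else NA)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "mapq",
                                   mapqFilter = as.integer(min_mapq))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  gr <- GenomicRanges::granges(ga)
  gr$mapq <- S4Vectors::mcols(ga)$mapq
  gr
}

#' Five-prime end of aligned reads
#'
#' The 5'-most aligned base of each read: the leftmost base for `+` strand
#' alignments, the rightmost for `-` strand.
#'
#' @param reads stranded `GRanges` of aligned spans.
#' @return `GRanges` of width-1 anchors (strand preserved).
#' @export
five_prime_end <- function(reads) {
  GenomicRanges::resize(reads, width = 1L, fix = "start")
}

#' Count reads in windows
#'
#' @param reads a `GRanges` of aligned spans (from [read_alignments()] or
#'   the simulator) or a path to an indexed BAM file.
#' @param windows `GRanges` of windows to count over.
#' @param mode `"overlap"` (>= 1 shared base) or `"five_prime"` (5' end
#'   inside the window).
#' @param min_mapq minimum mapping quality (applied when `reads` carries a
#'   `mapq` column or is a BAM path).
#' @param dedup drop duplicate-flagged reads (BAM input only).
#' @return Integer vector of counts, one per window. Reads are counted
#'   regardless of strand; unknown chromosomes yield zero counts with a
#'   warning.
#' @export
count_reads_in_window <- function(reads, windows,
                                  mode = c("overlap", "five_prime"),
                                  min_mapq = 0L, dedup = FALSE) {
  mode <- match.arg(mode)
  if (is.character(reads)) {
    reads <- read_alignments(reads, min_mapq = min_mapq, dedup = dedup)
  } else if (min_mapq > 0L && !is.null(reads$mapq)) {
    reads <- reads[!is.na(reads$mapq) & reads$mapq >= min_mapq]
  }
  if (length(windows) == 0L) return(integer(0))
  known <- as.character(GenomeInfoDb::seqnames(windows)) %in%
    unique(as.character(GenomeInfoDb::seqnames(reads)))
  if (length(reads) > 0L && !all(known))
    warning("windows on chromosomes absent from the read set count 0")
  anchors <- if (mode == "five_prime") five_prime_end(reads) else reads
  count_overlapping(windows, anchors)
}

#' TSS and gene-body counts for transcripts
#'
#' Derives the TSS and gene-body windows of each transcript and counts
#' reads in both with identical settings.
#'
#' @param reads `GRanges` of aligned spans or a BAM path.
#' @param tx stranded `GRanges` of transcripts (must pass the length
#'   filter: genomic span > `gb_offset`).
#' @param flank TSS window half-width (bp).
#' @param gb_offset gene-body start, bp downstream of the TSS.
#' @param gb_tail gene-body extension past the TES (bp).
#' @param mode,min_mapq,dedup passed to [count_reads_in_window()].
#' @param disjoint drop the boundary base shared by the two windows from
#'   the gene body.
#' @param chrom_length optional chromosome length(s) for window clamping.
#' @return `data.frame` with columns `transcript_id`, `tss_count`,
#'   `gb_count`, `tss_width`, `gb_width`.
#' @export
tss_gb_counts <- function(reads, tx, flank = 300L, gb_offset = 300L,
                          gb_tail = 3000L, mode = c("overlap", "five_prime"),
                          min_mapq = 0L, dedup = FALSE, disjoint = FALSE,
                          chrom_length = NULL) {
  mode <- match.arg(mode)
  if (is.character(reads))
    reads <- read_alignments(reads, min_mapq = min_mapq, dedup = dedup)
  tssw <- tss_window(tx, flank = flank, chrom_length = chrom_length)
  gbw <- genebody_window(tx, offset = gb_offset, tail = gb_tail,
                         disjoint = disjoint, chrom_length = chrom_length)
  data.frame(
    transcript_id = if (!is.null(tx$transcript_id))
      as.character(tx$transcript_id) else paste0("tx_", seq_along(tx)),
    tss_count = count_reads_in_window(reads, tssw, mode = mode,
                                      min_mapq = min_mapq),
    gb_count = count_reads_in_window(reads, gbw, mode = mode,
                                     min_mapq = min_mapq),
    tss_width = GenomicRanges::width(tssw),
    gb_width = GenomicRanges::width(gbw),
    stringsAsFactors = FALSE)
}
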