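## Peak lists: reading, significance filtering, replicate pooling, and the
## peak-at-TSS test used by the stalling-index filter cascade.
##
## Significance is carried as -log10(p) (`neg_log10_p`), the narrowPeak
## pValue column; raw p-value thresholds from the command line are converted
## once at the boundary. The printed analysis never states its p-value
## cutoff or pooling rule, so both are explicit arguments with conventional
## defaults (p <= 1e-5; union pooling).

#' Read peak calls from narrowPeak or BED
#'
#' narrowPeak (10-column) supplies `-log10(p)` from its pValue column;
#' plain BED3/BED6 carries no significance, so `neg_log10_p` defaults to 0
#' with a warning (such peaks survive only a zero threshold).
#'
#' @param path peak file.
#' @param format `"narrowPeak"` or `"bed"` (guessed from the extension when
#'   missing).
#' @param replicate_label optional label stored in a `replicate_label`
#'   metadata column.
#' @return `GRanges` with `score`, `neg_log10_p` and `replicate_label`
#'   metadata columns.
#' @export
read_peaks <- function(path, format = c("auto", "narrowPeak", "bed"),
                       replicate_label = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("narrowpeak$", tolower(path))) "narrowPeak" else "bed"
  }
  if (format == "narrowPeak") {
    gr <- rtracklayer::import(path, format = "narrowPeak")
    nlp <- if (length(gr)) as.numeric(gr$pValue) else numeric()
    if (any(nlp < 0, na.rm = TRUE))
      stop("narrowPeak pValue column must be -log10(p) >= 0")
    score <- if (!is.null(gr$score)) as.numeric(gr$score) else
      rep(0, length(gr))
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr))
      warning("BED peaks carry no significance column; neg_log10_p set to 0")
    nlp <- rep(0, length(gr))
    score <- if (!is.null(gr$score) && !anyNA(gr$score))
      as.numeric(gr$score) else rep(0, length(gr))
  }
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    score = score, neg_log10_p = nlp,
    replicate_label = rep(as.character(replicate_label), length(gr)))
  out
}

#' Filter peaks by significance
#'
#' Retains peaks with `neg_log10_p >= min_neg_log10_p`, preserving order.
#' Raising the threshold can only remove peaks (monotone).
#'
#' @param peaks `GRanges` with a `neg_log10_p` column.
#' @param min_neg_log10_p threshold on `-log10(p)`; use
#'   [p_to_neg_log10()] to convert a raw p-value cutoff.
#' @return Filtered `GRanges`.
#' @export
filter_peaks <- function(peaks, min_neg_log10_p) {
  stopifnot(min_neg_log10_p >= 0)
  if (is.null(peaks$neg_log10_p))
    stop("peaks must carry a neg_log10_p column (see read_peaks)")
  peaks[peaks$neg_log10_p >= min_neg_log10_p]
}

#' Convert a raw p-value threshold to -log10 scale
#'
#' @param p raw p-value in (0, 1].
#' @return `-log10(p)`.
#' @export
p_to_neg_log10 <- function(p) {
  stopifnot(p > 0, p <= 1)
  -log10(p)
}

#' Pool peak calls across replicates
#'
#' `union` mode merges all replicates' peaks into disjoint regions.
#' `support_k` mode keeps the maximal regions covered by peaks from at
#' least `k` distinct replicates (within a replicate, overlapping peaks
#' count once). Pooled regions carry `neg_log10_p` equal to the maximum
#' over the contributing peaks; `support_k` with `k = 1` equals union.
#'
#' @param replicate_peaks list of `GRanges`, one element per replicate.
#' @param mode `"union"` or `"support_k"`.
#' @param k minimum number of supporting replicates (`support_k` mode).
#' @return `GRanges` of pooled peaks with `score`, `neg_log10_p` and a
#'   provenance `name` column.
#' @export
pool_replicates <- function(replicate_peaks, mode = c("union", "support_k"),
                            k = 2L) {
  mode <- match.arg(mode)
  if (!is.list(replicate_peaks) || length(replicate_peaks) == 0L)
    stop("replicate_peaks must be a non-empty list of GRanges")
  if (mode == "support_k") {
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    if (k > length(replicate_peaks))
      stop("k (", k, ") exceeds the number of replicates (",
           length(replicate_peaks), ")")
  }
  all_peaks <- suppressWarnings(do.call(c, lapply(replicate_peaks,
                                                  GenomicRanges::granges)))
  if (mode == "union" || k == 1L) {
    pooled <- merge_intervals(all_peaks)
  } else {
    # per-base count of distinct replicates covering the base; a common
    # seqinfo keeps the per-replicate coverage Rles aligned before summing
    chrs <- unique(as.character(GenomeInfoDb::seqnames(all_peaks)))
    ends <- tapply(GenomicRanges::end(all_peaks),
                   as.character(GenomeInfoDb::seqnames(all_peaks)), max)
    si <- GenomeInfoDb::Seqinfo(chrs, as.integer(ends[chrs]) + 1L)
    per_rep <- lapply(replicate_peaks, function(p) {
      p <- GenomicRanges::reduce(GenomicRanges::granges(p),
                                 ignore.strand = TRUE)
      GenomeInfoDb::seqlevels(p) <- chrs
      suppressWarnings(GenomeInfoDb::seqinfo(p) <- si)
      p
    })
    cov <- Reduce(`+`, lapply(per_rep, GenomicRanges::coverage))
    pooled <- GenomicRanges::GRanges(IRanges::slice(cov, lower = k,
                                                    rangesOnly = TRUE))
    pooled <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(pooled),
                                     GenomicRanges::ranges(pooled),
                                     seqinfo = GenomeInfoDb::seqinfo(all_peaks))
  }
  if (length(pooled) == 0L) {
    S4Vectors::mcols(pooled) <- S4Vectors::DataFrame(
      name = character(), score = numeric(), neg_log10_p = numeric())
    return(pooled)
  }
  src <- all_peaks
  src_nlp <- unlist(lapply(replicate_peaks, function(p)
    if (is.null(p$neg_log10_p)) rep(0, length(p))
    else as.numeric(p$neg_log10_p)), use.names = FALSE)
  hits <- GenomicRanges::findOverlaps(pooled, src, ignore.strand = TRUE)
  nlp <- rep(0, length(pooled))
  agg <- tapply(src_nlp[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), max)
  nlp[as.integer(names(agg))] <- as.numeric(agg)
  n_src <- rep(0L, length(pooled))
  cnt <- table(S4Vectors::queryHits(hits))
  n_src[as.integer(names(cnt))] <- as.integer(cnt)
  S4Vectors::mcols(pooled) <- S4Vectors::DataFrame(
    name = sprintf("pooled_%s_%d_of_%d", mode, n_src, length(replicate_peaks)),
    score = nlp, neg_log10_p = nlp)
  pooled
}

#' Write pooled peaks as narrowPeak
#'
#' Ten-column narrowPeak with the pooled `-log10(p)` in the pValue column,
#' provenance in the name column, and `-1` sentinels for qValue/summit.
#'
#' @param peaks `GRanges` from [pool_replicates()] (or any peak set with a
#'   `neg_log10_p` column).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_narrowpeak <- function(peaks, path) {
  nlp <- if (!is.null(peaks$neg_log10_p)) as.numeric(peaks$neg_log10_p) else
    rep(0, length(peaks))
  name <- if (!is.null(peaks$name)) as.character(peaks$name) else
    paste0("peak_", seq_along(peaks))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = name,
    score = as.integer(pmin(1000, round(10 * nlp))),
    strand = ".",
    signalValue = nlp,
    pValue = nlp,
    qValue = -1,
    peak = -1L,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Test for a peak on the TSS
#'
#' `TRUE` for each transcript whose TSS window (`[tss - flank, tss + flank]`,
#' closed) overlaps at least one peak by one or more bases. Set `flank = 0`
#' for point overlap with the single TSS base.
#'
#' @param tx stranded `GRanges` of transcripts.
#' @param peaks `GRanges` of (filtered, pooled) peaks.
#' @param flank TSS window half-width in bp.
#' @return Logical vector, one per transcript.
#' @export
has_peak_at_tss <- function(tx, peaks, flank = 300L) {
  if (length(tx) == 0L) return(logical(0))
  win <- if (flank >= 1L) tss_window(tx, flank = flank) else {
    w <- tx
    GenomicRanges::ranges(w) <- IRanges::IRanges(tss_position(tx),
                                                 tss_position(tx))
    w
  }
  count_overlapping(win, peaks) > 0L
}
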