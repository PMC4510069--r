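## The stalling index and travelling ratio, with the filter cascade and
## distribution summaries.
##
## SI = TSS / GB, TR = GB / TSS, computed per transcript from raw read
## counts over the TSS and gene-body windows. SI is undefined (NA) when the
## gene-body count is zero, TR when the TSS count is zero; no pseudocount
## is added unless asked for. Only transcripts longer than 600 bp (strict)
## that carry an RNAPII peak on their TSS window receive an SI.

#' Stalling index from window counts
#'
#' `SI = tss_count / gb_count`, or, with `normalize_by_width = TRUE`, the
#' ratio of read densities `(tss_count/tss_width) / (gb_count/gb_width)`.
#' `NA` when the gene-body count is zero (no pseudocount by default; pass
#' `pseudocount > 0` to add it to both counts).
#'
#' @param tss_count,gb_count non-negative read counts (vectorised).
#' @param normalize_by_width use per-bp densities instead of raw counts.
#' @param tss_width,gb_width window widths in bp, required when
#'   `normalize_by_width = TRUE`.
#' @param pseudocount added to both counts before the ratio (default 0).
#' @return Numeric vector; `NA` where undefined.
#' @export
stalling_index <- function(tss_count, gb_count, normalize_by_width = FALSE,
                           tss_width = NULL, gb_width = NULL,
                           pseudocount = 0) {
  stopifnot(all(tss_count >= 0, na.rm = TRUE),
            all(gb_count >= 0, na.rm = TRUE), pseudocount >= 0)
  num <- tss_count + pseudocount
  den <- gb_count + pseudocount
  if (normalize_by_width) {
    if (is.null(tss_width) || is.null(gb_width))
      stop("normalize_by_width = TRUE requires tss_width and gb_width")
    num <- num / tss_width
    den <- den / gb_width
  }
  ifelse(den > 0, num / den, NA_real_)
}

#' Travelling ratio from window counts
#'
#' `TR = gb_count / tss_count`, the reciprocal convention of the stalling
#' index (the literature uses both orientations; both are reported and
#' labelled). `NA` when the TSS count is zero.
#'
#' @param tss_count,gb_count non-negative read counts (vectorised).
#' @param pseudocount added to both counts before the ratio (default 0).
#' @return Numeric vector; `NA` where undefined.
#' @export
travelling_ratio <- function(tss_count, gb_count, pseudocount = 0) {
  stopifnot(all(tss_count >= 0, na.rm = TRUE),
            all(gb_count >= 0, na.rm = TRUE), pseudocount >= 0)
  num <- gb_count + pseudocount
  den <- tss_count + pseudocount
  ifelse(den > 0, num / den, NA_real_)
}

#' Per-transcript stalling table
#'
#' The central computation: every transcript is annotated with its TSS and
#' gene-body read counts, the two filter flags (genomic span strictly above
#' `min_length`; at least one peak overlapping the TSS window), and SI/TR —
#' computed only for transcripts passing both filters, `NA` elsewhere.
#' Transcripts failing a filter are reported with flags rather than
#' dropped, so the filter cascade is auditable. Rows are sorted by
#' `transcript_id`.
#'
#' @param reads `GRanges` of aligned spans or a path to an indexed BAM.
#' @param tx stranded `GRanges` of transcripts with `transcript_id`.
#' @param peaks `GRanges` of RNAPII peaks, already significance-filtered
#'   and pooled.
#' @param flank TSS window half-width in bp (default 300).
#' @param gb_offset,gb_tail gene-body window parameters in bp (defaults
#'   300 and 3000).
#' @param min_length transcript-length filter in bp, strict (default 600).
#' @param mode counting mode, `"overlap"` or `"five_prime"`.
#' @param min_mapq,dedup,disjoint,chrom_length passed to the counting
#'   layer.
#' @param normalize_by_width report density-ratio SI instead of the raw
#'   count ratio.
#' @param pseudocount added to both counts before the ratios (default 0).
#' @return A `stalling_table`: a `data.frame` with columns
#'   `transcript_id`, `tss_count`, `gb_count`, `tss_width`, `gb_width`,
#'   `si`, `tr`, `passed_length`, `passed_peak`, carrying the parameters
#'   used as attributes. Has `print`, `summary`, `plot` and
#'   `as.data.frame` methods.
#' @export
compute_stalling_table <- function(reads, tx, peaks, flank = 300L,
                                   gb_offset = 300L, gb_tail = 3000L,
                                   min_length = 600L,
                                   mode = c("overlap", "five_prime"),
                                   min_mapq = 0L, dedup = FALSE,
                                   disjoint = FALSE, chrom_length = NULL,
                                   normalize_by_width = FALSE,
                                   pseudocount = 0) {
  mode <- match.arg(mode)
  if (length(tx) == 0L)
    return(new_stalling_table(empty_stalling_df(), params = list()))
  if (is.character(reads))
    reads <- read_alignments(reads, min_mapq = min_mapq, dedup = dedup)
  passed_length <- passes_length_filter(tx, min_length = min_length)
  passed_peak <- if (length(peaks) > 0L)
    has_peak_at_tss(tx, peaks, flank = flank) else rep(FALSE, length(tx))
  ids <- if (!is.null(tx$transcript_id)) as.character(tx$transcript_id) else
    paste0("tx_", seq_along(tx))

  tss_count <- gb_count <- rep(NA_integer_, length(tx))
  tss_width <- gb_width <- rep(NA_integer_, length(tx))
  # gene-body windows only exist for transcripts longer than the offset,
  # so counting is restricted to transcripts passing the length filter
  eligible <- passed_length
  if (any(eligible)) {
    cnt <- tss_gb_counts(reads, tx[eligible], flank = flank,
                         gb_offset = gb_offset, gb_tail = gb_tail,
                         mode = mode, min_mapq = min_mapq,
                         disjoint = disjoint, chrom_length = chrom_length)
    tss_count[eligible] <- cnt$tss_count
    gb_count[eligible] <- cnt$gb_count
    tss_width[eligible] <- cnt$tss_width
    gb_width[eligible] <- cnt$gb_width
  }
  keep <- passed_length & passed_peak
  si <- tr <- rep(NA_real_, length(tx))
  if (any(keep)) {
    si[keep] <- stalling_index(tss_count[keep], gb_count[keep],
                               normalize_by_width = normalize_by_width,
                               tss_width = tss_width[keep],
                               gb_width = gb_width[keep],
                               pseudocount = pseudocount)
    tr[keep] <- travelling_ratio(tss_count[keep], gb_count[keep],
                                 pseudocount = pseudocount)
  }
  df <- data.frame(transcript_id = ids, tss_count = tss_count,
                   gb_count = gb_count, tss_width = tss_width,
                   gb_width = gb_width, si = si, tr = tr,
                   passed_length = passed_length, passed_peak = passed_peak,
                   stringsAsFactors = FALSE)
  df <- df[order(df$transcript_id), , drop = FALSE]
  rownames(df) <- NULL
  params <- list(flank = flank, gb_offset = gb_offset, gb_tail = gb_tail,
                 min_length = min_length, mode = mode, min_mapq = min_mapq,
                 dedup = dedup, disjoint = disjoint,
                 normalize_by_width = normalize_by_width,
                 pseudocount = pseudocount)
  new_stalling_table(df, params = params)
}

empty_stalling_df <- function() {
  data.frame(transcript_id = character(), tss_count = integer(),
             gb_count = integer(), tss_width = integer(),
             gb_width = integer(), si = numeric(), tr = numeric(),
             passed_length = logical(), passed_peak = logical(),
             stringsAsFactors = FALSE)
}

new_stalling_table <- function(df, params) {
  structure(df, params = params,
            class = c("stalling_table", "data.frame"))
}

#' @export
print.stalling_table <- function(x, n = 10L, ...) {
  p <- attr(x, "params")
  cat("Stalling table:", nrow(x), "transcripts\n")
  if (length(p))
    cat(sprintf(
      "  windows: TSS +/-%d bp; GB [tss+%d, TES+%d]; length > %d bp; mode %s\n",
      p$flank, p$gb_offset, p$gb_tail, p$min_length, p$mode))
  nsi <- sum(!is.na(x$si))
  cat(sprintf("  %d passed length filter, %d have a TSS peak, %d with SI\n",
              sum(x$passed_length), sum(x$passed_peak), nsi))
  if (nsi > 0)
    cat(sprintf("  median SI = %.4g, median TR = %.4g\n",
                stats::median(x$si, na.rm = TRUE),
                stats::median(x$tr, na.rm = TRUE)))
  print(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' @method as.data.frame stalling_table
#' @export
as.data.frame.stalling_table <- function(x, ...) {
  class(x) <- "data.frame"
  attr(x, "params") <- NULL
  x
}

#' Summarise TSS, gene-body and SI distributions
#'
#' Over transcripts with a defined SI only: 5/25/50/75/95% quantiles of the
#' TSS counts, gene-body counts and SI, plus log10-spaced histogram bins
#' for the SI. This is the numeric backing of the three-panel distribution
#' figure.
#'
#' @param x a `stalling_table` (or any data.frame with `tss_count`,
#'   `gb_count`, `si`).
#' @param n_bins number of SI histogram bins (log10-spaced).
#' @return Object of class `si_summary`: list with `quantiles` (3 x 5
#'   matrix), `si_histogram` (`breaks` and `counts`), `n_defined`.
#' @export
si_distribution_summary <- function(x, n_bins = 30L) {
  ok <- !is.na(x$si)
  if (!any(ok)) {
    warning("no transcripts with a defined SI; empty summary")
    return(structure(list(quantiles = NULL, si_histogram = NULL,
                          n_defined = 0L), class = "si_summary"))
  }
  probs <- c(0.05, 0.25, 0.50, 0.75, 0.95)
  q <- rbind(
    tss_count = stats::quantile(x$tss_count[ok], probs, na.rm = TRUE),
    gb_count = stats::quantile(x$gb_count[ok], probs, na.rm = TRUE),
    si = stats::quantile(x$si[ok], probs))
  colnames(q) <- paste0("q", probs * 100)
  si <- x$si[ok & x$si > 0]
  histo <- NULL
  if (length(si) > 0) {
    rng <- range(log10(si))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- 10^seq(rng[1], rng[2], length.out = n_bins + 1L)
    counts <- as.integer(table(cut(si, breaks, include.lowest = TRUE)))
    histo <- list(breaks = breaks, counts = counts)
  }
  structure(list(quantiles = q, si_histogram = histo,
                 n_defined = sum(ok)), class = "si_summary")
}

#' @export
print.si_summary <- function(x, ...) {
  cat("SI distribution summary over", x$n_defined,
      "transcripts with defined SI\n")
  if (!is.null(x$quantiles)) print(round(x$quantiles, 4))
  invisible(x)
}

#' @method summary stalling_table
#' @export
summary.stalling_table <- function(object, ...) {
  si_distribution_summary(object)
}

#' Three-panel distribution figure
#'
#' Histograms of TSS counts, gene-body counts and SI (log10 axis), over
#' transcripts with a defined SI — the SI balances promoter loading
#' against gene-body travel, so the two count distributions are shown
#' alongside it.
#'
#' @param x a `stalling_table`.
#' @param ... ignored.
#' @return Invisibly, `x`.
#' @method plot stalling_table
#' @export
plot.stalling_table <- function(x, ...) {
  ok <- !is.na(x$si)
  if (!any(ok)) {
    warning("nothing to plot: no transcripts with a defined SI")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::hist(x$tss_count[ok], breaks = 30, main = "TSS reads",
                 xlab = "reads in TSS window", col = "grey70")
  graphics::hist(x$gb_count[ok], breaks = 30, main = "Gene-body reads",
                 xlab = "reads in GB window", col = "grey70")
  si <- x$si[ok & x$si > 0]
  graphics::hist(log10(si), breaks = 30, main = "Stalling index",
                 xlab = "log10 SI (TSS/GB)", col = "steelblue")
  graphics::abline(v = stats::median(log10(si)), lty = 2)
  invisible(x)
}

#' Write a stalling table as TSV
#'
#' @param x a `stalling_table`.
#' @param path output file.
#' @param header_comments optional character vector written as leading
#'   `#`-comment lines (used by the CLI to echo the effective
#'   configuration).
#' @return Invisibly, `path`.
#' @export
write_stalling_tsv <- function(x, path, header_comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comments))
    writeLines(paste0("# ", header_comments), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
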