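## Interval data model and overlap/counting engine.
##
## Regions are plain GRanges (1-based, closed), the standard Bioconductor
## currency; BED-family input is converted on read by the importers. Overlap
## requires at least one shared base: ranges that merely touch (BED half-open
## adjacency) do not overlap.

#' Construct validated genomic intervals
#'
#' Thin constructor around [GenomicRanges::GRanges()] that enforces the
#' invariants the rest of the package relies on: non-empty chromosome names
#' and strictly positive widths.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 1-based closed coordinates
#'   (`start <= end`; a 1-bp interval has `start == end`).
#' @param strand `"+"`, `"-"` or `"*"` (unstranded); recycled.
#' @param ... further metadata columns passed to `GRanges()`.
#' @return A `GRanges` object.
#' @examples
#' gi("chr1", 101, 200, "+")
#' @export
gi <- function(chrom, start, end, strand = "*", ...) {
  if (length(chrom) == 0L) return(GenomicRanges::GRanges())
  if (any(!nzchar(chrom))) stop("chromosome names must be non-empty")
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("start/end must be integral")
  if (any(end < start))
    stop("intervals must be non-empty (start <= end, 1-based closed)")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand, ...)
}

#' Pairwise interval overlap
#'
#' `TRUE` iff the two intervals are on the same chromosome and share at
#' least one base. Touching intervals (e.g. 1-100 and 101-200) do not
#' overlap. Strand is ignored unless `match_strand = TRUE`.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @param match_strand if `TRUE`, `+` and `-` intervals never overlap each
#'   other (`*` overlaps both).
#' @return Logical vector.
#' @export
gi_overlaps <- function(a, b, match_strand = FALSE) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  as.vector(IRanges::poverlaps(a, b, ignore.strand = !match_strand))
}

#' Count subjects overlapping each query
#'
#' For each query interval, the number of subject intervals sharing at
#' least one base with it (strand ignored by default, as ChIP-seq reads
#' are counted regardless of strand).
#'
#' @param queries,subjects `GRanges`.
#' @param match_strand if `TRUE`, only same-strand subjects are counted.
#' @return Integer vector, one count per query.
#' @export
count_overlapping <- function(queries, subjects, match_strand = FALSE) {
  GenomicRanges::countOverlaps(queries, subjects,
                               ignore.strand = !match_strand)
}

#' Merge overlapping intervals
#'
#' Collapses a set of intervals into the minimal sorted set of disjoint
#' intervals covering the same bases. Adjacent (touching) intervals are
#' merged as well, matching the semantics of pooling peak calls by union.
#'
#' @param x `GRanges`.
#' @return Sorted, disjoint `GRanges` (strand and metadata dropped).
#' @export
merge_intervals <- function(x) {
  GenomicRanges::reduce(GenomicRanges::granges(x), ignore.strand = TRUE,
                        min.gapwidth = 1L)
}

#' Clamp an interval to chromosome bounds
#'
#' Restricts intervals to `[1, chrom_length]`. An interval falling entirely
#' off the chromosome is an error: it signals a derived window that does
#' not exist on the sequence at all.
#'
#' @param x `GRanges`.
#' @param chrom_length positive integer, or a named vector of lengths
#'   indexed by chromosome.
#' @return Clamped `GRanges`.
#' @export
clamp_interval <- function(x, chrom_length) {
  if (is.null(names(chrom_length))) {
    len <- rep(as.integer(chrom_length[1L]), length(x))
  } else {
    len <- as.integer(chrom_length[as.character(GenomeInfoDb::seqnames(x))])
    if (any(is.na(len)))
      stop("no chromosome length supplied for some intervals")
  }
  if (any(len < 1L)) stop("chrom_length must be >= 1")
  s <- pmax(GenomicRanges::start(x), 1L)
  e <- pmin(GenomicRanges::end(x), len)
  if (any(e < s))
    stop("interval falls entirely outside the chromosome after clamping")
  GenomicRanges::ranges(x) <- IRanges::IRanges(s, e)
  x
}

#' Write intervals as BED6
#'
#' Serialises intervals in 6-column BED (0-based half-open on disk), mainly
#' for inspection of derived windows in a genome browser.
#'
#' @param x `GRanges`; a `name` and `score` metadata column are used when
#'   present.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_bed6 <- function(x, path) {
  name <- if (!is.null(x$name)) as.character(x$name) else
    paste0("region_", seq_along(x))
  score <- if (!is.null(x$score)) as.numeric(x$score) else rep(0, length(x))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x),
    name = name,
    score = score,
    strand = as.character(GenomicRanges::strand(x)),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
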