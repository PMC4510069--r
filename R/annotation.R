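## Transcript models and derivation of the TSS / gene-body windows.
##
## Definitions, in transcript orientation with closed endpoints:
##   TSS window:       [tss - flank, tss + flank]            (default 300 bp)
##   gene-body window: [tss + offset, TES + tail]            (default 300/3000)
## Both windows deliberately share the single base at tss + offset when
## flank == offset; `disjoint = TRUE` starts the gene body one base later.
## "Length" is genomic span, not spliced mature length; exon structure is
## never consulted.

#' Read transcript models from GTF or BED12
#'
#' Returns one record per transcript as a stranded `GRanges` with
#' `transcript_id` and `gene_id` metadata columns. GTF files must contain
#' `transcript` feature rows carrying a `transcript_id` attribute (1-based
#' closed coordinates, used as-is); BED12/BED6 files use the `name` column
#' as both transcript and gene id (0-based half-open converted on import).
#' Unstranded records are rejected: a TSS is undefined without a strand.
#'
#' @param path annotation file.
#' @param format `"gtf"` or `"bed12"` (guessed from the extension when
#'   missing).
#' @return `GRanges` with `transcript_id` and `gene_id` columns.
#' @export
read_transcripts <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff")) "gtf" else "bed12"
  }
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (file.size(path) == 0L)
    return(gi(character(), integer(), integer())[0])
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    if (length(gr) == 0L)
      return(gi(character(), integer(), integer())[0])
    if (!is.null(gr$type)) {
      tx <- gr[as.character(gr$type) == "transcript"]
      if (length(tx) == 0L) tx <- gr   # plain GTFs without a type hierarchy
    } else tx <- gr
    if (is.null(tx$transcript_id) || anyNA(tx$transcript_id))
      stop("GTF transcript records must carry a transcript_id attribute")
    gene <- if (!is.null(tx$gene_id)) as.character(tx$gene_id) else
      as.character(tx$transcript_id)
    gene[is.na(gene)] <- as.character(tx$transcript_id)[is.na(gene)]
    out <- GenomicRanges::granges(tx)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      transcript_id = as.character(tx$transcript_id), gene_id = gene)
  } else {
    bed <- rtracklayer::import(path, format = "bed")
    if (length(bed) == 0L)
      return(gi(character(), integer(), integer())[0])
    if (is.null(bed$name) || anyNA(bed$name))
      stop("BED12 transcript records must carry a name")
    out <- GenomicRanges::granges(bed)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      transcript_id = as.character(bed$name),
      gene_id = as.character(bed$name))
  }
  if (any(as.character(GenomicRanges::strand(out)) == "*"))
    stop("unstranded transcript records are not allowed (TSS undefined)")
  out
}

#' Transcription start site position
#'
#' The genomic coordinate (1-based) of the first transcribed base: the
#' interval start on the `+` strand, the interval end on the `-` strand.
#'
#' @param tx stranded `GRanges` of transcripts.
#' @return Integer vector of TSS coordinates.
#' @export
tss_position <- function(tx) {
  st <- as.character(GenomicRanges::strand(tx))
  if (any(st == "*")) stop("TSS undefined for unstranded transcripts")
  ifelse(st == "+", GenomicRanges::start(tx), GenomicRanges::end(tx))
}

#' TSS window of a transcript
#'
#' The closed interval `[tss - flank, tss + flank]`, width `2 * flank + 1`,
#' independent of strand, optionally clamped to chromosome bounds.
#'
#' @param tx stranded `GRanges` of transcripts.
#' @param flank half-width in bp (default 300).
#' @param chrom_length optional chromosome length(s) for clamping.
#' @return `GRanges` of TSS windows, metadata columns preserved.
#' @export
tss_window <- function(tx, flank = 300L, chrom_length = NULL) {
  stopifnot(flank >= 1L)
  tss <- tss_position(tx)
  win <- tx
  GenomicRanges::ranges(win) <- IRanges::IRanges(tss - as.integer(flank),
                                                 tss + as.integer(flank))
  if (!is.null(chrom_length)) win <- clamp_interval(win, chrom_length)
  win
}

#' Gene-body window of a transcript
#'
#' In transcription direction, the closed interval from `offset` bases
#' downstream of the TSS to `tail` bases past the transcription end site;
#' genomic width is `length - offset + tail`. On the `-` strand this maps to
#' genomic coordinates `[TES - tail, tss - offset]`. With the defaults
#' (`offset = 300`) the window shares exactly one base with the 300-bp TSS
#' window; `disjoint = TRUE` shifts the gene-body start one base downstream
#' for strict partition semantics.
#'
#' @param tx stranded `GRanges` of transcripts; every genomic span must
#'   exceed `offset` bp.
#' @param offset bp downstream of the TSS where the gene body starts
#'   (default 300).
#' @param tail bp past the transcription end site (default 3000).
#' @param disjoint drop the shared boundary base from the gene body.
#' @param chrom_length optional chromosome length(s) for clamping.
#' @return `GRanges` of gene-body windows, metadata columns preserved.
#' @export
genebody_window <- function(tx, offset = 300L, tail = 3000L,
                            disjoint = FALSE, chrom_length = NULL) {
  stopifnot(offset >= 1L, tail >= 1L)
  if (any(GenomicRanges::width(tx) <= offset))
    stop("transcript genomic span must exceed the gene-body offset (",
         offset, " bp); apply the length filter first")
  st <- as.character(GenomicRanges::strand(tx))
  tss <- tss_position(tx)
  shift <- if (disjoint) 1L else 0L
  plus <- st == "+"
  s <- ifelse(plus, tss + offset + shift,
              GenomicRanges::start(tx) - as.integer(tail))
  e <- ifelse(plus, GenomicRanges::end(tx) + as.integer(tail),
              tss - offset - shift)
  win <- tx
  GenomicRanges::ranges(win) <- IRanges::IRanges(s, e)
  if (!is.null(chrom_length)) win <- clamp_interval(win, chrom_length)
  win
}

#' Transcript length filter
#'
#' `TRUE` for transcripts whose genomic span strictly exceeds `min_length`
#' (default 600 bp; a 600-bp transcript fails, a 601-bp one passes).
#'
#' @param tx `GRanges` of transcripts.
#' @param min_length minimum span in bp, strict.
#' @return Logical vector.
#' @export
passes_length_filter <- function(tx, min_length = 600L) {
  GenomicRanges::width(tx) > min_length
}
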