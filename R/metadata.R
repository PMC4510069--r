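## Multi-assay sample-sheet model: parsing, baseline expansion, validation
## and querying.
##
## The sheet mirrors the deposited study's inventory: one row per
## sequencing sample with a replicate field ("2/3" = replicate 2 of 3), a
## data type (ChIP-Seq / RNA-Seq / DNAse-Seq), an optional target, an
## organism code mapping to a genome build (mmu -> mm9, hsa -> hg18), a
## biological model, and zero or more baseline/input references — possibly
## as a dash-ranged accession like "GSM1234734-7". Null cells are "-" or
## the typographic en dash. A transcribed copy of the study's 94-sample
## sheet ships with the package (see `stallr_example_sheet()`).

NULL_MARKS <- c("-", "–", "—", "", NA)

is_null_mark <- function(x) x %in% NULL_MARKS

#' Path to the packaged 94-sample sheet
#'
#' @return Path to the TSV fixture transcribed from the study inventory.
#' @export
stallr_example_sheet <- function() {
  system.file("extdata", "gse51011_samples.tsv", package = "stallr",
              mustWork = TRUE)
}

#' Parse a sample sheet
#'
#' Reads a UTF-8 TSV with columns `sample_id`, `sample_name`, `rep`,
#' `data_type`, `target`, `org`, `biological_model`, `baseline`. Replicate
#' fields `i/n` are split into `replicate_index` / `replicate_total`; null
#' markers become `NA` (target) or an empty baseline list; ranged baseline
#' references are expanded via [expand_baseline_reference()]. Model names
#' get an ASCII alias (`model_ascii`, e.g. the Greek mu transliterated to
#' "u") for robust matching, with the original preserved.
#'
#' @param path TSV file.
#' @return `data.frame` with one row per sample; `baseline_ids` is a list
#'   column of character vectors; `genome` is derived from `org`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  required <- c("sample_id", "sample_name", "rep", "data_type", "target",
                "org", "biological_model", "baseline")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("sample sheet lacks columns: ", paste(missing, collapse = ", "))
  rep_parts <- regmatches(df$rep, regexec("^([0-9]+)/([0-9]+)$", df$rep))
  bad <- vapply(rep_parts, length, 1L) != 3L
  if (any(bad))
    stop("malformed replicate field in row(s) ",
         paste(which(bad), collapse = ", "), " (expected i/n)")
  df$replicate_index <- vapply(rep_parts, function(m) as.integer(m[2]), 1L)
  df$replicate_total <- vapply(rep_parts, function(m) as.integer(m[3]), 1L)
  if (any(df$replicate_index < 1L | df$replicate_index > df$replicate_total))
    stop("replicate_index must lie in 1..replicate_total")
  known_types <- c("ChIP-Seq", "RNA-Seq", "DNAse-Seq")
  if (any(!df$data_type %in% known_types))
    stop("unknown data_type: ",
         paste(unique(setdiff(df$data_type, known_types)), collapse = ", "))
  genomes <- c(mmu = "mm9", hsa = "hg18")
  if (any(!df$org %in% names(genomes)))
    stop("unknown organism code: ",
         paste(unique(setdiff(df$org, names(genomes))), collapse = ", "))
  df$genome <- unname(genomes[df$org])
  df$target_raw <- df$target
  df$target[is_null_mark(df$target)] <- NA_character_
  df$baseline_ids <- lapply(df$baseline, expand_baseline_reference)
  df$model_ascii <- ascii_model(df$biological_model)
  df
}

ascii_model <- function(x) gsub("μ", "u", x)

#' Expand a baseline accession reference
#'
#' Accepts a single accession (`"GSM1395178"`), a dash-ranged accession
#' with a truncated right endpoint (`"GSM1234734-7"`, meaning GSM1234734
#' through GSM1234737), or a null marker (`"-"` / en dash), which expands
#' to an empty vector. In the ranged form the digits after the dash
#' replace the same number of trailing digits of the left accession and
#' must yield a larger number.
#'
#' @param ref a single reference string.
#' @return Character vector of accessions (possibly empty).
#' @export
expand_baseline_reference <- function(ref) {
  stopifnot(length(ref) == 1L)
  if (is_null_mark(ref)) return(character())
  if (length(regmatches(ref, regexec("^[A-Za-z]+[0-9]+$", ref))[[1]]))
    return(ref)
  parts <- regmatches(ref, regexec("^([A-Za-z]+)([0-9]+)-([0-9]+)$", ref))[[1]]
  if (length(parts) != 4L)
    stop("unrecognised baseline reference: ", ref)
  prefix <- parts[2]; left <- parts[3]; right <- parts[4]
  if (nchar(right) >= nchar(left))
    stop("ranged reference right endpoint longer than left: ", ref)
  stem <- substr(left, 1L, nchar(left) - nchar(right))
  from <- as.numeric(left)
  to <- as.numeric(paste0(stem, right))
  if (to <= from)
    stop("ranged reference does not increase: ", ref)
  width <- nchar(left)
  sprintf(paste0("%s%0", width, "d"), prefix, seq(from, to))
}

## Replicate-set grouping: strip trailing replicate markers from the sample
## name (a ".B" suffix, trailing digits, then a trailing separator), e.g.
## "X.Myc.P.2" -> "X.Myc.P", "X.H3K4me3.C1" -> "X.H3K4me3.C",
## "X.RNAseq.C_3" -> "X.RNAseq.C", "X.DNAseI.0hOHT.B" -> "X.DNAseI.0hOHT".
replicate_group_key <- function(name) {
  key <- sub("\\.B$", "", name)
  key <- sub("[0-9]+$", "", key)
  sub("[._]$", "", key)
}

#' Validate a sample sheet
#'
#' Cross-checks the sheet's internal linkage and returns issues as data,
#' not exceptions. ERROR-level issues: duplicate `sample_id`; a baseline
#' reference not present in the sheet; replicate sets (rows declaring a
#' shared name stem and `replicate_total > 1`) whose observed indices are
#' not exactly `1..total`; rows declaring `1/1` with index != 1.
#' WARNING-level: input rows (empty baseline, name containing "input")
#' that nonetheless list a target — the printed inventory contains such
#' rows and they are preserved verbatim.
#'
#' @param records `data.frame` from [read_sample_sheet()].
#' @return `data.frame` with columns `level` ("ERROR"/"WARNING"),
#'   `sample_id`, `issue`; zero rows means the sheet is valid.
#' @export
validate_sheet <- function(records) {
  issues <- list()
  add <- function(level, id, msg)
    issues[[length(issues) + 1L]] <<- data.frame(
      level = level, sample_id = id, issue = msg, stringsAsFactors = FALSE)

  dup <- records$sample_id[duplicated(records$sample_id)]
  for (d in unique(dup)) add("ERROR", d, "duplicate sample_id")

  ids <- records$sample_id
  for (i in seq_len(nrow(records))) {
    dangling <- setdiff(records$baseline_ids[[i]], ids)
    for (d in dangling)
      add("ERROR", records$sample_id[i],
          paste0("baseline ", d, " not present in the sheet"))
  }

  key <- replicate_group_key(records$sample_name)
  multi <- records$replicate_total > 1L
  for (k in unique(key[multi])) {
    sel <- multi & key == k
    totals <- unique(records$replicate_total[sel])
    idx <- sort(records$replicate_index[sel])
    if (length(totals) != 1L || !identical(idx, seq_len(totals[1]))) {
      add("ERROR", records$sample_id[sel][1],
          paste0("replicate set '", k, "' declares total ",
                 paste(totals, collapse = "/"), " but observes indices ",
                 paste(idx, collapse = ",")))
    }
  }

  is_input <- lengths(records$baseline_ids) == 0L &
    grepl("input", records$sample_name, ignore.case = TRUE)
  odd <- is_input & !is.na(records$target)
  for (i in which(odd))
    add("WARNING", records$sample_id[i],
        paste0("input row lists a target (", records$target[i],
               "); preserved verbatim from the source inventory"))

  if (length(issues) == 0L)
    return(data.frame(level = character(), sample_id = character(),
                      issue = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Query a sample sheet
#'
#' Conjunctive filter on biological model, data type and/or target, in
#' stable (input) order. Model matching uses the ASCII alias, so
#' `"Eu-myc"` matches the Greek-mu original.
#'
#' @param records `data.frame` from [read_sample_sheet()].
#' @param model,data_type,target optional filter values (`NULL` = no
#'   filter on that field).
#' @return Filtered `data.frame`.
#' @export
query_samples <- function(records, model = NULL, data_type = NULL,
                          target = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(model))
    keep <- keep & (records$model_ascii == ascii_model(model))
  if (!is.null(data_type)) keep <- keep & records$data_type == data_type
  if (!is.null(target))
    keep <- keep & !is.na(records$target) & records$target == target
  records[keep, , drop = FALSE]
}

#' Write a sample sheet
#'
#' Inverse of [read_sample_sheet()]: serialises the original columns back
#' to TSV (derived columns are dropped), so `write(read(x))` reproduces
#' `x` up to whitespace.
#'
#' @param records `data.frame` from [read_sample_sheet()].
#' @param path output TSV.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(records, path) {
  cols <- c("sample_id", "sample_name", "rep", "data_type", "target",
            "org", "biological_model", "baseline")
  out <- records[, cols]
  if (!is.null(records$target_raw)) out$target <- records$target_raw
  else out$target[is.na(out$target)] <- "–"
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
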