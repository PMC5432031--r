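# The long time-course table: one row per
# (gene_id, condition, replicate, timepoint) with an FPKM (or normalized)
# value. All quantitative modules consume and return this shape.

validate_timecourse <- function(tc, what = "time course") {
  check_columns(tc, c("gene_id", "condition", "replicate", "timepoint",
                      "value"), what)
  if (nrow(tc) > 0) {
    grids <- tc |>
      dplyr::group_by(.data$condition, .data$replicate) |>
      dplyr::summarise(
        grid = paste(sort(unique(.data$timepoint)), collapse = ","),
        .groups = "drop"
      )
    if (length(unique(grids$grid)) > 1L) {
      rlang::abort("all conditions/replicates must share one timepoint grid")
    }
    if (any(tc$timepoint < 0)) {
      rlang::abort("timepoints must be non-negative minutes")
    }
  }
  invisible(tc)
}

timecourse_scale <- function(tc) attr(tc, "scale", exact = TRUE) %||% "fpkm"

set_timecourse_scale <- function(tc, scale) {
  attr(tc, "scale") <- scale
  tc
}

#' Read / write long time-course tables
#'
#' TSV with columns `gene_id`, `condition`, `replicate`, `timepoint`, `value`
#' (timepoints in minutes). This is the on-disk form of every FPKM and
#' normalized table in the package.
#'
#' @param path File path.
#' @return `read_timecourse()`: a validated tibble. `write_timecourse()`:
#'   `path`, invisibly.
#' @export
read_timecourse <- function(path) {
  tc <- readr::read_tsv(path, show_col_types = FALSE)
  validate_timecourse(tc)
  tc
}

#' @param tc Long time-course tibble.
#' @rdname read_timecourse
#' @export
write_timecourse <- function(tc, path) {
  validate_timecourse(tc)
  readr::write_tsv(tc, path)
  invisible(path)
}

#' Read / write FASTQ
#'
#' Thin wrappers over Biostrings turning FASTQ records into the package's
#' read table and back. Qualities are carried through unchanged where present
#' (writing emits constant qualities when none are attached).
#'
#' @param path FASTQ path (uncompressed or gzip).
#' @return `read_fastq()`: a read table. `write_fastq()`: `path`, invisibly.
#' @export
read_fastq <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    rlang::abort("read_fastq() requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  reads <- read_table(
    read_id = names(seqs) %||% paste0("read_", seq_along(seqs)),
    sequence = as.character(seqs)
  )
  q <- S4Vectors::mcols(seqs)$qualities
  reads$quality <- if (!is.null(q)) as.character(q) else NA_character_
  reads
}

#' @param reads Read table (optionally with a `quality` column).
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    rlang::abort("write_fastq() requires the Biostrings package")
  }
  check_columns(reads, c("read_id", "sequence"), "reads")
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  qual <- reads$quality %||% rep(NA_character_, nrow(reads))
  if (anyNA(qual)) {
    qual <- ifelse(is.na(qual),
                   strrep("I", nchar(reads$sequence)), qual)
  }
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}
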