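# Strand-aware per-nucleotide pileups and FPKM quantification.

#' Build a strand-aware pileup
#'
#' Computes per-nucleotide coverage over a genomic window from single-location
#' alignments. Only reads on the window's strand contribute (CRAC reads are
#' sense to the bound RNA); reads on the other strand are ignored, and reads
#' with no overlap at all are counted in a skipped-read tally.
#'
#' @param reads Read table with exactly one alignment per read (see
#'   [assign_multimappers()]).
#' @param region Either a one-row gene annotation (its transcribed span is
#'   used) or a list/tibble with `chrom`, `strand`, `start`, `end`
#'   (0-based half-open).
#' @param library_size Total mapped reads in the library the pileup is scaled
#'   against downstream; defaults to `nrow(reads)`.
#' @return A tibble of class `crac_pileup` with columns `pos` (0-based
#'   genomic) and `coverage`, and attributes `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `library_size`, `n_skipped`.
#' @export
build_pileup <- function(reads, region, library_size = NULL) {
  check_columns(reads, c("read_id", "chrom", "start", "end", "strand"),
                "reads")
  if (anyDuplicated(reads$read_id)) {
    rlang::abort("build_pileup() requires one alignment per read; run assign_multimappers() first")
  }
  if (all(c("tss", "end3") %in% names(region))) {
    region <- validate_annotation(as_tibble(region))
    span <- gene_span(region[1, ])
    scope <- list(gene_id = region$gene_id[1], chrom = region$chrom[1],
                  strand = region$strand[1],
                  start = span[["start"]], end = span[["end"]])
  } else {
    scope <- as.list(region)
    scope$gene_id <- scope$gene_id %||% NA_character_
  }
  if (!is_scalar_number(scope$start) || !is_scalar_number(scope$end) ||
      scope$start >= scope$end) {
    rlang::abort("invalid region: need start < end")
  }
  len <- scope$end - scope$start
  cov <- numeric(len)
  same <- !is.na(reads$chrom) & reads$chrom == scope$chrom &
    reads$strand == scope$strand
  overlapping <- same & reads$end > scope$start & reads$start < scope$end
  n_skipped <- sum(same & !overlapping)
  if (any(overlapping)) {
    # difference-array interval stabbing
    s <- pmax(reads$start[overlapping], scope$start) - scope$start
    e <- pmin(reads$end[overlapping], scope$end) - scope$start
    delta <- numeric(len + 1L)
    for (i in seq_along(s)) {
      delta[s[i] + 1L] <- delta[s[i] + 1L] + 1
      delta[e[i] + 1L] <- delta[e[i] + 1L] - 1
    }
    cov <- cumsum(delta)[seq_len(len)]
  }
  new_pileup(
    coverage = cov, gene_id = scope$gene_id, chrom = scope$chrom,
    strand = scope$strand, start = scope$start,
    library_size = library_size %||% length(unique(reads$read_id)),
    n_skipped = n_skipped
  )
}

#' Construct a pileup track from a coverage vector
#'
#' Low-level constructor for the per-nucleotide coverage container used by the
#' escape-index, peak-calling and profile functions.
#'
#' @param coverage Non-negative numeric vector, one entry per nucleotide.
#' @param gene_id,chrom,strand Scope of the track.
#' @param start 0-based genomic position of the first entry.
#' @param library_size Total mapped reads backing the track (positive).
#' @param n_skipped Reads skipped while building the track.
#' @return A `crac_pileup` tibble (columns `pos`, `coverage`).
#' @export
new_pileup <- function(coverage, gene_id = NA_character_,
                       chrom = NA_character_, strand = "+", start = 0,
                       library_size = NULL, n_skipped = 0L) {
  if (any(coverage < 0)) rlang::abort("coverage must be non-negative")
  if (!strand %in% c("+", "-")) rlang::abort("strand must be '+' or '-'")
  library_size <- library_size %||% max(1, sum(coverage))
  if (!is_scalar_number(library_size) || library_size <= 0) {
    rlang::abort("library_size must be a positive number")
  }
  out <- tibble(pos = start + seq_along(coverage) - 1, coverage = coverage)
  class(out) <- c("crac_pileup", class(out))
  attr(out, "gene_id") <- gene_id
  attr(out, "chrom") <- chrom
  attr(out, "strand") <- strand
  attr(out, "start") <- start
  attr(out, "end") <- start + length(coverage)
  attr(out, "library_size") <- library_size
  attr(out, "n_skipped") <- n_skipped
  out
}

pileup_attr <- function(pileup, what) attr(pileup, what, exact = TRUE)

#' @export
print.crac_pileup <- function(x, ...) {
  cat(sprintf(
    "<crac_pileup> %s %s:%s-%s (%s) library_size=%s total=%s\n",
    pileup_attr(x, "gene_id") %||% "?", pileup_attr(x, "chrom") %||% "?",
    format(pileup_attr(x, "start")), format(pileup_attr(x, "end")),
    pileup_attr(x, "strand"), format(pileup_attr(x, "library_size")),
    format(sum(x$coverage))
  ))
  NextMethod()
}

#' Write a pileup as bedGraph
#'
#' Exports a pileup track to bedGraph (0-based half-open, one line per run of
#' equal coverage) via `rtracklayer::export()`.
#'
#' @param pileup A `crac_pileup`.
#' @param path Output path (`.bedGraph` / `.bg`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(pileup, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    rlang::abort("write_bedgraph() requires the rtracklayer package")
  }
  r <- rle(pileup$coverage)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gr <- GenomicRanges::GRanges(
    seqnames = pileup_attr(pileup, "chrom") %||% "chr",
    ranges = IRanges::IRanges(start = pileup$pos[starts] + 1,
                              end = pileup$pos[ends] + 1),
    score = r$values
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Compute FPKM values
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM = count / (length_kb * library_size_millions)`. Genes present in
#' `lengths` but absent from `counts` get 0.
#'
#' @param counts Data frame with columns `gene_id`, `count`.
#' @param lengths Data frame with columns `gene_id`, `length_nt` (all > 0);
#'   a gene annotation tibble works directly.
#' @param library_size Total mapped reads (> 0).
#' @return Tibble with columns `gene_id`, `count`, `length_nt`, `fpkm`.
#' @examples
#' compute_fpkm(tibble::tibble(gene_id = "g1", count = 1),
#'              tibble::tibble(gene_id = "g1", length_nt = 1000),
#'              library_size = 1e6)
#' @export
compute_fpkm <- function(counts, lengths, library_size) {
  check_columns(counts, c("gene_id", "count"), "counts")
  check_columns(lengths, c("gene_id", "length_nt"), "lengths")
  if (!is_scalar_number(library_size) || library_size <= 0) {
    rlang::abort("library_size must be a positive number")
  }
  if (any(lengths$length_nt <= 0)) {
    bad <- lengths$gene_id[lengths$length_nt <= 0]
    rlang::abort(paste0("non-positive length for gene(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  out <- dplyr::left_join(
    dplyr::select(lengths, "gene_id", "length_nt"),
    dplyr::select(counts, "gene_id", "count"),
    by = "gene_id"
  )
  out$count <- ifelse(is.na(out$count), 0, out$count)
  out$fpkm <- out$count / ((out$length_nt / 1e3) * (library_size / 1e6))
  dplyr::select(as_tibble(out), "gene_id", "count", "length_nt", "fpkm")
}

#' Drop transcripts not detected at every timepoint
#'
#' The time-course analyses only consider genes for which cross-linking was
#' detected in every sample: any transcript with a zero or missing FPKM at any
#' (condition, replicate, timepoint) is removed. The removed gene set is
#' attached as the `"removed"` attribute and reported.
#'
#' @param tc Long time-course tibble with columns `gene_id`, `condition`,
#'   `replicate`, `timepoint`, `value`.
#' @param quiet Suppress the removal message.
#' @return The filtered tibble, with attribute `removed`.
#' @export
filter_detected_all_timepoints <- function(tc, quiet = FALSE) {
  validate_timecourse(tc)
  bad <- tc |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(drop = any(is.na(.data$value) | .data$value <= 0)) |>
    dplyr::filter(.data$drop)
  out <- dplyr::filter(tc, !.data$gene_id %in% bad$gene_id)
  if (!quiet && nrow(bad) > 0) {
    rlang::inform(paste0("filter_detected_all_timepoints: removed ",
                         nrow(bad), " transcript(s)"))
  }
  attr(out, "removed") <- bad$gene_id
  out
}
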