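# Read-level processing: demultiplexing by in-read barcodes, random-barcode
# (UMI) duplicate collapsing, and random placement of multimapping reads.
#
# Reads are plain tibbles, one row per candidate alignment:
#   read_id, sequence, umi, sample_barcode, chrom, start, end, strand,
#   soft_clip3
# Unaligned reads carry NA in the alignment columns. A read with several rows
# (same read_id, different loci) is a multimapper.

read_cols <- c("read_id", "sequence", "umi", "sample_barcode",
               "chrom", "start", "end", "strand", "soft_clip3")

#' Construct a read table
#'
#' Builds the tibble representation of sequencing reads used by the read-level
#' functions: one row per candidate alignment (0-based half-open coordinates),
#' several rows for a multimapping read, `NA` alignment columns for an
#' unaligned read.
#'
#' @param read_id,sequence Character vectors (recycled against the longest).
#' @param umi Random-barcode (UMI) portion of the in-read barcode; `""` before
#'   demultiplexing.
#' @param sample_barcode Sample-code portion of the in-read barcode.
#' @param chrom,start,end,strand Alignment coordinates (0-based half-open) and
#'   strand (`"+"`/`"-"`).
#' @param soft_clip3 Unaligned ("soft-clipped") bases at the read's 3' end,
#'   as sequenced; used by [detect_oligoA()].
#' @return A tibble with the standard read columns.
#' @export
read_table <- function(read_id, sequence = "", umi = "", sample_barcode = "",
                       chrom = NA_character_, start = NA_real_, end = NA_real_,
                       strand = NA_character_, soft_clip3 = "") {
  reads <- tibble(
    read_id = as.character(read_id), sequence = as.character(sequence),
    umi = as.character(umi), sample_barcode = as.character(sample_barcode),
    chrom = as.character(chrom), start = as.numeric(start),
    end = as.numeric(end), strand = as.character(strand),
    soft_clip3 = as.character(soft_clip3)
  )
  aligned <- !is.na(reads$chrom)
  if (any(aligned & !(reads$start < reads$end), na.rm = TRUE)) {
    rlang::abort("alignment start must be < end")
  }
  reads
}

# Parse a barcode layout string such as "NNNAGCNN": N marks a random-barcode
# (UMI) position, A/C/G/T mark fixed sample-code positions.
parse_barcode_layout <- function(layout) {
  chars <- strsplit(toupper(layout), "")[[1]]
  if (length(chars) == 0L || !all(chars %in% c("A", "C", "G", "T", "N"))) {
    rlang::abort(paste0("malformed barcode layout: '", layout, "'"))
  }
  list(
    width = length(chars),
    umi_pos = which(chars == "N"),
    code_pos = which(chars != "N"),
    code = paste(chars[chars != "N"], collapse = "")
  )
}

#' Demultiplex reads by their in-read barcodes
#'
#' Each library read starts with an in-read barcode that interleaves random
#' (UMI) bases with a fixed sample code. The barcode table gives one layout
#' string per sample, e.g. `"NNNAGCNN"`: `N` positions are random bases, the
#' remaining letters are the sample code. Reads are assigned to the unique
#' sample whose code matches the corresponding prefix positions, the barcode
#' is stripped from the sequence, and the UMI and sample code are recorded.
#' Non-matching reads are kept in an `"unassigned"` bin, never dropped.
#'
#' @param reads Read table (see [read_table()]); `sequence` must carry the raw
#'   5' bases including the barcode.
#' @param barcode_table Data frame with columns `sample` and `layout`. All
#'   layouts must have the same length and distinct sample codes.
#' @param max_mismatch Number of mismatches tolerated in the sample code
#'   (0 = exact matching, 1 = Hamming-1). A read matching more than one sample
#'   at the allowed distance goes to `"unassigned"`.
#' @return The read table with a `sample` column, barcode bases stripped from
#'   `sequence`, and `umi`/`sample_barcode` populated for assigned reads.
#' @examples
#' reads <- read_table(c("r1", "r2"), sequence = c("AGCTTTT", "TGACCCC"))
#' bc <- tibble::tibble(sample = c("S1", "S2"), layout = c("AGC", "TGA"))
#' demultiplex(reads, bc)
#' @export
demultiplex <- function(reads, barcode_table, max_mismatch = 0) {
  check_columns(reads, c("read_id", "sequence"), "reads")
  check_columns(barcode_table, c("sample", "layout"), "barcode_table")
  layouts <- lapply(barcode_table$layout, parse_barcode_layout)
  widths <- vapply(layouts, `[[`, numeric(1), "width")
  if (length(unique(widths)) != 1L) {
    rlang::abort("all barcode layouts must have the same length")
  }
  codes <- vapply(layouts, `[[`, character(1), "code")
  if (anyDuplicated(codes)) {
    rlang::abort("duplicate sample codes in barcode table")
  }
  if (nrow(reads) == 0L) {
    return(dplyr::mutate(reads, sample = character(0)))
  }
  width <- widths[[1]]
  prefix <- substr(reads$sequence, 1L, width)
  prefix_mat <- do.call(rbind, strsplit(format(prefix, width = width), ""))
  # mismatch count of each read's prefix against each sample's code positions
  mm <- vapply(seq_along(layouts), function(i) {
    lay <- layouts[[i]]
    code_chars <- strsplit(lay$code, "")[[1]]
    sub <- prefix_mat[, lay$code_pos, drop = FALSE]
    rowSums(sub != matrix(code_chars, nrow(sub), length(code_chars),
                          byrow = TRUE)) +
      ifelse(nchar(reads$sequence) < width, Inf, 0)
  }, numeric(nrow(reads)))
  mm <- matrix(mm, nrow = nrow(reads))
  ok <- mm <= max_mismatch
  n_hits <- rowSums(ok)
  best <- max.col(-mm, ties.method = "first")
  # ambiguous matches (possible with overlapping layouts or Hamming-1 mode)
  # are left unassigned rather than arbitrarily resolved
  assigned <- n_hits == 1L
  sample <- ifelse(assigned, barcode_table$sample[best], "unassigned")

  out <- reads
  out$sample <- sample
  hit <- sample != "unassigned"
  if (any(hit)) {
    lay_for <- layouts[best]
    out$umi[hit] <- vapply(which(hit), function(j) {
      p <- lay_for[[j]]$umi_pos
      if (length(p) == 0L) "" else paste(prefix_mat[j, p], collapse = "")
    }, character(1))
    out$sample_barcode[hit] <- codes[best[hit]]
    out$sequence[hit] <- substr(out$sequence[hit], width + 1L, 1e9L)
  }
  out
}

#' Collapse PCR duplicates using random barcodes
#'
#' PCR amplification of a cDNA library produces duplicate reads that share
#' both their random barcode (UMI) and their cDNA. One representative is kept
#' per duplicate key: `(umi, sequence)` in `"sequence"` mode (the
#' pre-alignment pipeline order) or `(umi, chrom, start, end, strand)` in
#' `"position"` mode. The per-key multiplicity is reported in `n_dup`.
#'
#' @param reads Read table with `umi` populated (non-empty).
#' @param mode `"sequence"` (default) or `"position"`.
#' @return The collapsed read table with an added `n_dup` column.
#' @export
collapse_duplicates <- function(reads, mode = c("sequence", "position")) {
  mode <- match.arg(mode)
  check_columns(reads, read_cols, "reads")
  if (nrow(reads) == 0L) {
    return(dplyr::mutate(reads, n_dup = integer(0)))
  }
  bad <- is.na(reads$umi) | reads$umi == ""
  if (any(bad)) {
    rlang::abort(paste0(
      "missing UMI for read(s): ",
      paste(utils::head(reads$read_id[bad], 5), collapse = ", ")
    ))
  }
  if (mode == "sequence") {
    key <- paste(reads$umi, reads$sequence, sep = "\r")
  } else {
    miss <- is.na(reads$chrom)
    if (any(miss)) {
      rlang::abort(paste0(
        "position mode requires alignments; unaligned read(s): ",
        paste(utils::head(reads$read_id[miss], 5), collapse = ", ")
      ))
    }
    key <- paste(reads$umi, reads$chrom, reads$start, reads$end,
                 reads$strand, sep = "\r")
  }
  keep <- !duplicated(key)
  out <- reads[keep, , drop = FALSE]
  out$n_dup <- as.integer(table(key)[key[keep]])
  out
}

#' Randomly place multimapping reads
#'
#' Reads that align equally well to several genomic locations are distributed
#' uniformly at random over their candidate locations, one location per read.
#' The choice is deterministic given `seed`.
#'
#' @param reads Read table; every read must have at least one alignment row.
#' @param seed Integer seed for the placement draw.
#' @return A read table with exactly one row (alignment) per `read_id`.
#' @export
assign_multimappers <- function(reads, seed) {
  check_columns(reads, read_cols, "reads")
  if (any(is.na(reads$chrom))) {
    bad <- unique(reads$read_id[is.na(reads$chrom)])
    rlang::abort(paste0("read(s) without alignment: ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (nrow(reads) == 0L) return(reads)
  with_seed(seed, {
    # stable order, then one uniform draw per read
    idx <- order(match(reads$read_id, unique(reads$read_id)))
    reads <- reads[idx, , drop = FALSE]
    picked <- unlist(lapply(split(seq_len(nrow(reads)), reads$read_id),
                            function(i) if (length(i) == 1L) i else sample(i, 1L)),
                     use.names = FALSE)
    dplyr::arrange(reads[sort(picked), , drop = FALSE],
                   match(.data$read_id, unique(reads$read_id)))
  })
}
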