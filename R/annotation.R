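#' Build a gene annotation table
#'
#' Assembles and validates the minimal transcript annotation used throughout
#' the package: one row per gene with chromosome, strand, transcription start
#' site (TSS) and 3' end. `tss` is the 0-based genomic position of the first
#' transcribed nucleotide; `end3` is the position one *past* the last
#' transcribed nucleotide in the direction of transcription (so on the minus
#' strand `tss > end3`). `length_nt = abs(end3 - tss)` is then the exact gene
#' length of the half-open span walked from the TSS towards the 3' end.
#'
#' @param gene_id Character vector of gene identifiers (unique).
#' @param chrom Character vector of chromosome / contig names.
#' @param strand `"+"` or `"-"` per gene.
#' @param tss 0-based genomic position of the TSS.
#' @param end3 0-based genomic position of the 3' end.
#'
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tss`, `end3`,
#'   `length_nt`.
#' @examples
#' gene_annotation("YAL001C", "chrI", "+", tss = 100, end3 = 1600)
#' @export
gene_annotation <- function(gene_id, chrom, strand, tss, end3) {
  ann <- tibble(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    strand = as.character(strand),
    tss = as.numeric(tss), end3 = as.numeric(end3)
  )
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  check_columns(ann, c("gene_id", "chrom", "strand", "tss", "end3"),
                "annotation")
  if (anyDuplicated(ann$gene_id)) {
    rlang::abort("annotation gene_id values must be unique")
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    rlang::abort("annotation strand must be '+' or '-'")
  }
  bad <- (ann$strand == "+" & ann$tss >= ann$end3) |
    (ann$strand == "-" & ann$tss <= ann$end3)
  if (any(bad)) {
    rlang::abort(paste0(
      "TSS/3' end inconsistent with strand for: ",
      paste(ann$gene_id[bad], collapse = ", ")
    ))
  }
  ann$length_nt <- abs(ann$end3 - ann$tss)
  ann
}

# Genomic half-open [start, end) span of a gene.
# "+": [tss, end3); "-": [end3 + 1, tss + 1). Both have length length_nt.
gene_span <- function(ann_row) {
  if (ann_row$strand == "+") {
    c(start = ann_row$tss, end = ann_row$end3)
  } else {
    c(start = ann_row$end3 + 1, end = ann_row$tss + 1)
  }
}

# Map positions relative to the TSS (5' anchor; negative = upstream on the
# coding strand) to genomic coordinates, strand-aware.
rel_to_genomic <- function(rel, tss, strand) {
  if (strand == "+") tss + rel else tss - rel
}

genomic_to_rel <- function(pos, tss, strand) {
  if (strand == "+") pos - tss else tss - pos
}

#' Read a transcript annotation from GTF/GFF3 or BED
#'
#' Thin wrapper over `rtracklayer::import()`. GTF/GFF (1-based, closed) is
#' converted to the package's internal 0-based coordinates on ingest; BED is
#' already 0-based half-open. One row per feature is returned, with the TSS
#' and 3' end derived from strand.
#'
#' @param path Path to a `.gtf`, `.gff`/`.gff3` or `.bed` file.
#' @param feature For GTF/GFF, which `type` to keep (default `"gene"`;
#'   set `NULL` to keep all records).
#' @return A gene annotation tibble (see [gene_annotation()]).
#' @export
read_annotation <- function(path, feature = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    rlang::abort("read_annotation() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  meta <- as_tibble(as.data.frame(gr))
  if (!is.null(feature) && "type" %in% names(meta)) {
    meta <- dplyr::filter(meta, as.character(.data$type) %in% feature)
  }
  id <- meta$gene_id %||% meta$name %||% meta$ID %||%
    paste0("feature_", seq_len(nrow(meta)))
  # rtracklayer reports 1-based closed starts for every dialect it imports;
  # first/last transcribed base in 0-based coordinates:
  first0 <- meta$start - 1
  last0 <- meta$end - 1
  strand <- as.character(meta$strand)
  if (any(strand == "*")) {
    rlang::abort("annotation features must be stranded")
  }
  gene_annotation(
    gene_id = id, chrom = as.character(meta$seqnames), strand = strand,
    tss = ifelse(strand == "+", first0, last0),
    end3 = ifelse(strand == "+", last0 + 1, first0 - 1)
  )
}
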