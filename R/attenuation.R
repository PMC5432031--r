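# Escape-index screening for transcription attenuation. The escape index
# (EI) measures the change, between a reference sample (t = 0) and a later
# or perturbed sample, of the ratio of promoter-proximal to gene-body read
# density. Genes tightly controlled by a terminator show Pol II pileups in
# the promoter-proximal region (PPR); when control is relieved the pileup
# dissolves into the gene body and the EI rises.

# Strand-aware genomic half-open window of a named region relative to the
# 5' anchor (TSS). PPR: relative -100 .. +250 (351 nt); body: +251 .. 3' end.
region_window <- function(ann_row, region = c("ppr", "body", "whole"),
                          ppr_upstream = 100, ppr_downstream = 250) {
  region <- match.arg(region)
  rel <- switch(region,
    ppr = c(-ppr_upstream, ppr_downstream + 1),
    body = c(ppr_downstream + 1, ann_row$length_nt),
    whole = c(0, ann_row$length_nt)
  )
  if (rel[2] <= rel[1]) {
    rlang::abort(paste0("gene ", ann_row$gene_id,
                        " too short for region '", region, "'"))
  }
  if (ann_row$strand == "+") {
    c(start = ann_row$tss + rel[1], end = ann_row$tss + rel[2])
  } else {
    c(start = ann_row$tss - rel[2] + 1, end = ann_row$tss - rel[1] + 1)
  }
}

#' Library-normalized read density of a gene region
#'
#' Sums the per-nucleotide coverage over the promoter-proximal region
#' (`"ppr"`, -100 to +250 nt around the 5' anchor), the gene body
#' (`"body"`, +251 nt to the 3' end) or the whole gene, divides by the
#' region length (reads/nt) and scales per million mapped reads. Windows
#' extending past the pileup are truncated with a warning.
#'
#' @param pileup A `crac_pileup` covering (at least part of) the gene locus.
#' @param annotation One-row gene annotation.
#' @param region `"ppr"`, `"body"` or `"whole"`.
#' @param library_size Total mapped reads; defaults to the pileup's
#'   `library_size` attribute.
#' @param ppr_upstream,ppr_downstream PPR bounds relative to the 5' anchor
#'   (defaults -100 / +250).
#' @return Density in coverage per nt per million mapped reads.
#' @export
region_density <- function(pileup, annotation,
                           region = c("ppr", "body", "whole"),
                           library_size = NULL,
                           ppr_upstream = 100, ppr_downstream = 250) {
  region <- match.arg(region)
  annotation <- validate_annotation(as_tibble(annotation))[1, ]
  if (region == "body" && annotation$length_nt <= ppr_downstream + 1) {
    rlang::abort(paste0("gene ", annotation$gene_id,
                        " too short for a body region"))
  }
  win <- region_window(annotation, region, ppr_upstream, ppr_downstream)
  library_size <- library_size %||% pileup_attr(pileup, "library_size")
  if (!is_scalar_number(library_size) || library_size <= 0) {
    rlang::abort("library_size must be a positive number")
  }
  p0 <- pileup$pos[1]
  p1 <- pileup$pos[nrow(pileup)] + 1
  lo <- max(win[["start"]], p0)
  hi <- min(win[["end"]], p1)
  if (lo > win[["start"]] || hi < win[["end"]]) {
    rlang::warn(paste0("region '", region, "' of ", annotation$gene_id,
                       " truncated to pileup extent"))
  }
  if (hi <= lo) return(0)
  sel <- pileup$pos >= lo & pileup$pos < hi
  mass <- sum(pileup$coverage[sel])
  (mass / (win[["end"]] - win[["start"]])) * 1e6 / library_size
}

#' Escape index of one gene between two samples
#'
#' `EI = [ppr(t) / body(t)] / [ppr(0) / body(0)]`, where `ppr` and `body`
#' are library-normalized region densities in the later/perturbed sample
#' (`pileup_t`) and the reference sample (`pileup_t0`). The per-sample
#' library scaling cancels inside each ratio, so the EI is invariant to
#' rescaling either pileup. The whole-gene density ratio
#' `transcription_change = whole(t) / whole(0)` is reported alongside.
#'
#' @param pileup_t0,pileup_t `crac_pileup`s of the same locus at the
#'   reference timepoint and the comparison timepoint.
#' @param annotation One-row gene annotation.
#' @param fpkm_t0,fpkm_t Optional FPKM values of the gene in the two samples
#'   (from [compute_fpkm()]); their mean is carried into the result for the
#'   coverage threshold of [select_attenuated()].
#' @param ... Passed to [region_density()] (`ppr_upstream`,
#'   `ppr_downstream`, `library_size` is taken from each pileup).
#' @return One-row tibble: `gene_id`, `ppr_density_t0`, `ppr_density_t`,
#'   `body_density_t0`, `body_density_t`, `ratio_t0`, `ratio_t`, `ei`,
#'   `transcription_change`, `mean_fpkm`, `resolved`.
#' @export
escape_index <- function(pileup_t0, pileup_t, annotation,
                         fpkm_t0 = NA_real_, fpkm_t = NA_real_, ...) {
  annotation <- validate_annotation(as_tibble(annotation))[1, ]
  d <- function(p, region) region_density(p, annotation, region, ...)
  ppr0 <- d(pileup_t0, "ppr");  ppr1 <- d(pileup_t, "ppr")
  body0 <- d(pileup_t0, "body"); body1 <- d(pileup_t, "body")
  whole0 <- d(pileup_t0, "whole"); whole1 <- d(pileup_t, "whole")
  resolved <- body0 > 0 && body1 > 0
  ratio0 <- if (body0 > 0) ppr0 / body0 else NA_real_
  ratio1 <- if (body1 > 0) ppr1 / body1 else NA_real_
  ei <- if (resolved && ratio0 > 0) ratio1 / ratio0 else NA_real_
  if (!resolved) {
    rlang::warn(paste0("gene ", annotation$gene_id,
                       " unresolved: zero body density"))
  }
  tibble(
    gene_id = annotation$gene_id,
    ppr_density_t0 = ppr0, ppr_density_t = ppr1,
    body_density_t0 = body0, body_density_t = body1,
    ratio_t0 = ratio0, ratio_t = ratio1, ei = ei,
    transcription_change = if (whole0 > 0) whole1 / whole0 else NA_real_,
    mean_fpkm = mean(c(fpkm_t0, fpkm_t), na.rm = TRUE),
    resolved = resolved
  )
}

#' Select candidate attenuated genes
#'
#' Applies the screening thresholds to a table of escape-index results:
#' coverage of at least `min_fpkm` FPKM, an increase in transcription of at
#' least `min_change`, and an EI of at least `min_ei` (all boundary
#' inclusive). When a peak table is supplied, genes must additionally have at
#' least one binding-site peak overlapping their promoter-proximal region;
#' when replicate results are supplied, the EI threshold must hold in both.
#'
#' @param results Tibble of [escape_index()] rows (one per gene).
#' @param annotations Gene annotation tibble (needed only with `peaks`).
#' @param min_fpkm,min_change,min_ei Selection thresholds (defaults 10, 1.5,
#'   2).
#' @param peaks Optional peak tibble from [call_peaks()].
#' @param replicate_results Optional second [escape_index()] table from a
#'   replicate experiment.
#' @param ppr_upstream,ppr_downstream PPR bounds used for the peak-overlap
#'   criterion.
#' @return `results` with a logical `selected` column.
#' @export
select_attenuated <- function(results, annotations = NULL, min_fpkm = 10,
                              min_change = 1.5, min_ei = 2, peaks = NULL,
                              replicate_results = NULL,
                              ppr_upstream = 100, ppr_downstream = 250) {
  check_columns(results, c("gene_id", "ei", "transcription_change",
                           "mean_fpkm"), "results")
  sel <- !is.na(results$ei) & results$ei >= min_ei &
    !is.na(results$transcription_change) &
    results$transcription_change >= min_change &
    !is.na(results$mean_fpkm) & results$mean_fpkm >= min_fpkm
  if (!is.null(peaks)) {
    if (is.null(annotations)) {
      rlang::abort("peak criterion requires annotations")
    }
    annotations <- validate_annotation(as_tibble(annotations))
    has_ppr_peak <- vapply(results$gene_id, function(g) {
      ann <- annotations[annotations$gene_id == g, ]
      if (nrow(ann) == 0) return(FALSE)
      win <- region_window(ann[1, ], "ppr", ppr_upstream, ppr_downstream)
      any(peaks$chrom == ann$chrom[1] & peaks$strand == ann$strand[1] &
            peaks$end > win[["start"]] & peaks$start < win[["end"]])
    }, logical(1))
    sel <- sel & has_ppr_peak
  }
  if (!is.null(replicate_results)) {
    rep_ei <- replicate_results$ei[
      match(results$gene_id, replicate_results$gene_id)]
    sel <- sel & !is.na(rep_ei) & rep_ei >= min_ei
  }
  dplyr::mutate(results, selected = sel)
}
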