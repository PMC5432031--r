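# Binding-site (peak) calling on per-nucleotide pileups and detection of
# reads carrying non-encoded oligo(A) tails, the hallmark of NNS-exosome
# degradation intermediates.

#' Call binding-site peaks on a pileup
#'
#' Finds maximal contiguous intervals whose per-nucleotide coverage is at
#' least `min_reads` and whose width is at least `min_width` nt. When read
#' lengths are supplied, each gene is additionally assigned an empirical
#' false discovery rate from a within-gene uniform read-placement permutation
#' null: in each of `n_perm` permutations the same reads are re-placed
#' uniformly over the region, peaks are re-called with the same constraints,
#' and `FDR = mean(null peak count) / observed peak count`, clipped to
#' `[0, 1]`. The permutation is deterministic given `seed`.
#'
#' @param pileup A `crac_pileup` (see [build_pileup()]).
#' @param min_reads Minimum peak height in reads (default 5).
#' @param min_width Minimum peak width in nt (default 20).
#' @param count_mode `"height"` (default): `min_reads` constrains the maximum
#'   coverage in the interval; `"total"`: it constrains the total coverage
#'   mass.
#' @param read_lengths Integer vector of the lengths of the reads underlying
#'   the pileup; required for the permutation FDR (`NA` FDR otherwise).
#' @param fdr_threshold Drop peaks whose FDR exceeds this value (`NULL` = no
#'   filtering).
#' @param n_perm Number of permutations (default 100).
#' @param seed Seed for the permutation null (required with `read_lengths`).
#' @return Tibble of peaks: `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open genomic), `width`, `max_height`, `total_reads`
#'   (total coverage mass), `fdr`.
#' @export
call_peaks <- function(pileup, min_reads = 5, min_width = 20,
                       count_mode = c("height", "total"),
                       read_lengths = NULL, fdr_threshold = NULL,
                       n_perm = 100, seed = NULL) {
  count_mode <- match.arg(count_mode)
  if (min_width < 1) rlang::abort("min_width must be >= 1")
  check_columns(pileup, c("pos", "coverage"), "pileup")
  start0 <- pileup_attr(pileup, "start") %||% pileup$pos[1]
  peaks <- scan_peaks(pileup$coverage, min_reads, min_width, count_mode)
  out <- tibble(
    gene_id = pileup_attr(pileup, "gene_id") %||% NA_character_,
    chrom = pileup_attr(pileup, "chrom") %||% NA_character_,
    strand = pileup_attr(pileup, "strand") %||% "+",
    start = start0 + peaks$start, end = start0 + peaks$end,
    width = peaks$end - peaks$start,
    max_height = peaks$max_height, total_reads = peaks$total,
    fdr = NA_real_
  )
  if (!is.null(read_lengths) && nrow(out) > 0) {
    if (is.null(seed)) {
      rlang::abort("permutation FDR requires an explicit seed")
    }
    len <- nrow(pileup)
    null_counts <- with_seed(seed, {
      vapply(seq_len(n_perm), function(p) {
        starts <- floor(runif(length(read_lengths), 0,
                              pmax(1, len - read_lengths + 1)))
        delta <- numeric(len + 1L)
        for (i in seq_along(starts)) {
          e <- min(len, starts[i] + read_lengths[i])
          delta[starts[i] + 1L] <- delta[starts[i] + 1L] + 1
          delta[e + 1L] <- delta[e + 1L] - 1
        }
        cov <- cumsum(delta)[seq_len(len)]
        nrow(scan_peaks(cov, min_reads, min_width, count_mode))
      }, numeric(1))
    })
    out$fdr <- min(1, mean(null_counts) / nrow(out))
    if (!is.null(fdr_threshold)) {
      out <- dplyr::filter(out, .data$fdr <= fdr_threshold)
    }
  }
  out
}

# Exhaustive run-scan: maximal intervals with coverage >= min_reads
# ("height" mode); width filter applied after maximality.
scan_peaks <- function(coverage, min_reads, min_width, count_mode = "height") {
  above <- coverage >= min_reads & coverage > 0
  if (count_mode == "total") {
    # candidate intervals are maximal runs of non-zero coverage whose total
    # mass reaches min_reads
    above <- coverage > 0
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  s <- starts[keep]
  e <- ends[keep]
  res <- tibble(
    start = s - 1L, end = e,
    max_height = vapply(seq_along(s), function(i)
      max(coverage[s[i]:e[i]]), numeric(1)),
    total = vapply(seq_along(s), function(i)
      sum(coverage[s[i]:e[i]]), numeric(1))
  )
  if (count_mode == "total") {
    res <- dplyr::filter(res, .data$total >= min_reads)
  }
  dplyr::filter(res, .data$end - .data$start >= min_width)
}

#' Detect reads with non-encoded oligo(A) tails
#'
#' A read is reported when the soft-clipped bases at its 3' end (strand
#' oriented, i.e. as sequenced on the transcribed strand) form a run of at
#' least `min_tail` adenosines AND the reference bases immediately downstream
#' of the alignment's 3' end are not an A-run of the same length on the
#' transcribed strand. Genomically encoded A-runs are thereby suppressed:
#' only template-free additions (degradation intermediates) remain.
#'
#' @param reads Single-alignment read table with `soft_clip3` populated.
#' @param genome Named character vector of contig sequences (names =
#'   chromosomes), or anything `as.character()`-coercible to one.
#' @param min_tail Minimum tail length in nt (default 3).
#' @return Tibble: `read_id`, `chrom`, `strand`, `genomic_end` (0-based
#'   position of the last aligned base at the 3' end), `tail_seq`,
#'   `tail_len`, `encoded` (always `FALSE` for reported tails).
#' @export
detect_oligoA <- function(reads, genome, min_tail = 3) {
  check_columns(reads, c("read_id", "chrom", "start", "end", "strand",
                         "soft_clip3"), "reads")
  genome <- vapply(genome, as.character, character(1))
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    rlang::abort("genome must be a named vector of contig sequences")
  }
  clip <- toupper(reads$soft_clip3 %||% "")
  clip[is.na(clip)] <- ""
  is_tail <- nchar(clip) >= min_tail &
    clip == strrep("A", nchar(clip)) & nchar(clip) > 0
  hits <- which(is_tail)
  if (length(hits) == 0L) {
    return(tibble(read_id = character(0), chrom = character(0),
                  strand = character(0), genomic_end = numeric(0),
                  tail_seq = character(0), tail_len = integer(0),
                  encoded = logical(0)))
  }
  res <- purrr::map_dfr(hits, function(i) {
    chrom <- reads$chrom[i]
    if (!chrom %in% names(genome)) {
      rlang::abort(paste0("reference sequence unavailable for contig ",
                          chrom))
    }
    contig <- genome[[chrom]]
    tl <- nchar(clip[i])
    if (reads$strand[i] == "+") {
      # downstream = genomic positions end .. end + tl - 1 (0-based)
      from <- reads$end[i] + 1           # 1-based substring index
      down <- substr(contig, from, from + tl - 1)
      encoded <- toupper(down) == strrep("A", tl)
      gend <- reads$end[i] - 1
    } else {
      # downstream on the transcribed strand = genomic start - 1 downwards;
      # A on the transcript corresponds to T on the reference plus strand
      to <- reads$start[i]               # 1-based index of start - 1 is start
      down <- substr(contig, max(1, to - tl + 1), to)
      encoded <- toupper(down) == strrep("T", tl) && nchar(down) == tl
      gend <- reads$start[i]
    }
    tibble(read_id = reads$read_id[i], chrom = chrom,
           strand = reads$strand[i], genomic_end = gend,
           tail_seq = clip[i], tail_len = tl, encoded = encoded)
  })
  dplyr::filter(res, !.data$encoded)
}

#' Per-nucleotide track of oligo(A) tail termini
#'
#' Counts, for each nucleotide of a region, how many detected oligo(A) tails
#' have their 3' terminus (last aligned base) at that position.
#'
#' @param tails Output of [detect_oligoA()].
#' @param region List/tibble with `chrom`, `strand`, `start`, `end` (0-based
#'   half-open), or a one-row gene annotation.
#' @return A `crac_pileup` whose `coverage` is the per-position terminus
#'   count.
#' @export
oligoA_track <- function(tails, region) {
  if (all(c("tss", "end3") %in% names(region))) {
    region <- validate_annotation(as_tibble(region))[1, ]
    span <- gene_span(region)
    scope <- list(gene_id = region$gene_id, chrom = region$chrom,
                  strand = region$strand, start = span[["start"]],
                  end = span[["end"]])
  } else {
    scope <- as.list(region)
    scope$gene_id <- scope$gene_id %||% NA_character_
  }
  len <- scope$end - scope$start
  cov <- numeric(len)
  if (nrow(tails) > 0) {
    sel <- tails$chrom == scope$chrom & tails$strand == scope$strand &
      tails$genomic_end >= scope$start & tails$genomic_end < scope$end
    idx <- tails$genomic_end[sel] - scope$start + 1
    tab <- table(idx)
    cov[as.integer(names(tab))] <- as.numeric(tab)
  }
  new_pileup(cov, gene_id = scope$gene_id, chrom = scope$chrom,
             strand = scope$strand, start = scope$start,
             library_size = max(1, nrow(tails)))
}
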