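# Temporal-profile filtering and K-means clustering, TSS-aligned coverage
# matrices, TSS-centered binding-site distributions, and length-normalized
# meta-profiles.

#' Filter temporal profiles for clustering
#'
#' Retains transcripts whose replicate-averaged relative binding changes at
#' least `min_fold`-fold at some timepoint (fold-change = max of the ratio
#' and its inverse, so 0.5 and 2.0 both count as 2-fold) and whose replicate
#' time series have a mean pairwise Pearson correlation of at least
#' `min_corr`. The replicate-averaged log2 profile of every retained
#' transcript is returned.
#'
#' @param ntc Baseline-normalized long tibble ([relative_to_baseline()] or
#'   [to_log2()] output), typically restricted to one condition first.
#' @param min_fold Minimum max fold-change (default 1.5).
#' @param min_corr Minimum mean pairwise replicate correlation (default 0.7).
#' @return A tibble of class `profile_set`, one row per retained
#'   (transcript, timepoint): `gene_id`, `timepoint`, `profile` (mean log2
#'   fold-change), plus per-gene `max_fold` and `replicate_cor`. The per-gene
#'   statistics for *all* transcripts are in the `"stats"` attribute.
#' @export
filter_profiles <- function(ntc, min_fold = 1.5, min_corr = 0.7) {
  validate_timecourse(ntc)
  n_rep <- length(unique(ntc$replicate))
  if (n_rep < 2 && min_corr > -1) {
    rlang::abort("replicate correlation filter requires >= 2 replicates")
  }
  lin <- if (identical(timecourse_scale(ntc), "log2")) {
    dplyr::mutate(ntc, value = 2^.data$value)
  } else ntc
  stats <- lin |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      wide <- d |>
        dplyr::group_by(.data$replicate, .data$timepoint) |>
        dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
        tidyr::pivot_wider(names_from = "replicate", values_from = "value") |>
        dplyr::arrange(.data$timepoint)
      mat <- as.matrix(wide[, -1, drop = FALSE])
      avg <- rowMeans(mat)
      max_fold <- max(pmax(avg, 1 / avg))
      cors <- suppressWarnings(cor(mat))
      mean_cor <- mean(cors[upper.tri(cors)])
      tibble(max_fold = max_fold, replicate_cor = mean_cor)
    }) |>
    dplyr::ungroup()
  kept <- stats |>
    dplyr::filter(.data$max_fold >= min_fold,
                  !is.na(.data$replicate_cor),
                  .data$replicate_cor >= min_corr)
  profiles <- lin |>
    dplyr::filter(.data$gene_id %in% kept$gene_id) |>
    dplyr::group_by(.data$gene_id, .data$timepoint) |>
    dplyr::summarise(profile = log2(mean(.data$value)), .groups = "drop") |>
    dplyr::left_join(kept, by = "gene_id")
  class(profiles) <- c("profile_set", class(profiles))
  attr(profiles, "stats") <- stats
  profiles
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# each next center drawn with probability proportional to the squared
# distance to the nearest chosen center.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      centers[j + 1] <- sample.int(n, 1)
    } else {
      centers[j + 1] <- sample.int(n, 1, prob = d2)
    }
    dj <- rowSums((X - matrix(X[centers[j + 1], ], n, ncol(X),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  X[centers, , drop = FALSE]
}

#' K-means clustering of temporal profiles
#'
#' Lloyd's algorithm with k-means++ seeding on the replicate-averaged log2
#' profiles, Euclidean distance, deterministic given `seed`.
#'
#' @param profiles A `profile_set` from [filter_profiles()] (or any long
#'   tibble with `gene_id`, `timepoint`, `profile`).
#' @param k Number of clusters (1 <= k <= number of transcripts).
#' @param seed Integer seed for the seeding draw.
#' @param max_iter Maximum Lloyd iterations (default 100).
#' @return An object of class `kincrac_kmeans`: list with `assignments`
#'   (tibble `gene_id`, `cluster`), `centroids` (tibble `cluster`,
#'   `timepoint`, `profile`), `inertia`, `iter`, `converged`, `k`.
#'   [tidy()] returns the assignments, [glance()] the fit summary.
#' @export
kmeans_cluster <- function(profiles, k, seed, max_iter = 100) {
  check_columns(profiles, c("gene_id", "timepoint", "profile"), "profiles")
  wide <- profiles |>
    dplyr::select("gene_id", "timepoint", "profile") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "profile") |>
    dplyr::arrange(match(.data$gene_id, unique(profiles$gene_id)))
  X <- as.matrix(wide[, -1, drop = FALSE])
  n <- nrow(X)
  if (k < 1 || k > n) rlang::abort("k must be between 1 and n transcripts")
  fit <- with_seed(seed, {
    init <- kmeanspp_init(X, k)
    # duplicate initial centers break stats::kmeans; nudge deterministically
    while (anyDuplicated(init)) {
      dup <- which(duplicated(init))
      init[dup, ] <- init[dup, , drop = FALSE] +
        matrix(rnorm(length(dup) * ncol(init), 0, 1e-8),
               nrow = length(dup))
    }
    suppressWarnings(
      kmeans(X, centers = init, iter.max = max_iter, algorithm = "Lloyd")
    )
  })
  tps <- as.numeric(colnames(X))
  centroids <- as_tibble(fit$centers) |>
    dplyr::mutate(cluster = seq_len(k) - 1L) |>
    tidyr::pivot_longer(-"cluster", names_to = "timepoint",
                        values_to = "profile") |>
    dplyr::mutate(timepoint = as.numeric(.data$timepoint))
  structure(
    list(
      assignments = tibble(gene_id = wide$gene_id,
                           cluster = fit$cluster - 1L),
      centroids = centroids,
      inertia = fit$tot.withinss,
      iter = fit$iter,
      converged = fit$iter < max_iter,
      k = k
    ),
    class = "kincrac_kmeans"
  )
}

#' @export
print.kincrac_kmeans <- function(x, ...) {
  cat(sprintf("<kincrac_kmeans> k = %d, n = %d, inertia = %.4g%s\n",
              x$k, nrow(x$assignments), x$inertia,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @rdname kmeans_cluster
#' @param x A `kincrac_kmeans` object.
#' @param ... Unused.
#' @export
tidy.kincrac_kmeans <- function(x, ...) x$assignments

#' @rdname kmeans_cluster
#' @export
glance.kincrac_kmeans <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$assignments), inertia = x$inertia,
         iter = x$iter, converged = x$converged)
}

#' TSS-aligned coverage matrix
#'
#' Arranges per-gene coverage into a genes-by-positions table aligned at the
#' TSS: column 0 is the TSS, negative positions are upstream on the coding
#' strand (strand-aware on both strands). Rows are sorted by transcript
#' length. Cells outside a gene's available coverage are `NA` (missing, as
#' distinct from zero coverage).
#'
#' @param coverage Long tibble with columns `gene_id`, `pos` (0-based
#'   genomic) and `coverage`; a single `crac_pileup` also works (its gene
#'   scope is used), or bind several with their gene ids.
#' @param annotations Gene annotation tibble.
#' @param window Half-width of the relative-position window in nt (columns
#'   `-window .. +window`).
#' @return Long tibble `gene_id`, `rel_pos`, `value`, with genes ordered by
#'   increasing length (use `tidyr::pivot_wider()` for the matrix form).
#' @export
tss_aligned_matrix <- function(coverage, annotations, window = 500) {
  if (inherits(coverage, "crac_pileup")) {
    coverage <- dplyr::mutate(as_tibble(coverage),
                              gene_id = pileup_attr(coverage, "gene_id"))
  }
  check_columns(coverage, c("gene_id", "pos", "coverage"), "coverage")
  annotations <- validate_annotation(as_tibble(annotations))
  annotations <- dplyr::arrange(annotations, .data$length_nt)
  rel <- seq(-window, window)
  out <- purrr::map_dfr(seq_len(nrow(annotations)), function(i) {
    ann <- annotations[i, ]
    gpos <- rel_to_genomic(rel, ann$tss, ann$strand)
    cov <- coverage[coverage$gene_id == ann$gene_id, ]
    if (nrow(cov) == 0) {
      rlang::warn(paste0("no coverage for gene ", ann$gene_id))
      return(tibble(gene_id = ann$gene_id, rel_pos = rel,
                    value = NA_real_))
    }
    tibble(gene_id = ann$gene_id, rel_pos = rel,
           value = cov$coverage[match(gpos, cov$pos)])
  })
  out
}

#' TSS-centered binding-site distribution
#'
#' For each gene, binding-site positions are mapped to TSS-relative
#' coordinates and normalized to a within-gene frequency (each gene's sites
#' sum to 1); the per-gene frequencies are then summed across genes into one
#' distribution vector. Genes without sites contribute zeros.
#'
#' @param sites Tibble with columns `gene_id`, `pos` (0-based genomic site
#'   position, e.g. a peak summit).
#' @param annotations Gene annotation tibble.
#' @param window Half-width of the relative window (sites outside are
#'   discarded before normalization).
#' @return Tibble `rel_pos`, `frequency` covering `-window .. +window`.
#' @export
tss_site_distribution <- function(sites, annotations, window = 500) {
  check_columns(sites, c("gene_id", "pos"), "sites")
  annotations <- validate_annotation(as_tibble(annotations))
  rel <- seq(-window, window)
  acc <- numeric(length(rel))
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    s <- sites[sites$gene_id == ann$gene_id, ]
    if (nrow(s) == 0) next
    rp <- genomic_to_rel(s$pos, ann$tss, ann$strand)
    rp <- rp[rp >= -window & rp <= window]
    if (length(rp) == 0) next
    tab <- table(factor(rp, levels = rel))
    acc <- acc + as.numeric(tab) / length(rp)
  }
  tibble(rel_pos = rel, frequency = acc)
}

#' Compare two binding-site distributions
#'
#' Two-sample Kolmogorov-Smirnov test on samples of TSS-relative site
#' positions: `D = max |ECDF_a - ECDF_b|` with the asymptotic two-sided
#' p-value.
#'
#' @param positions_a,positions_b Numeric samples of relative positions
#'   (non-empty).
#' @return Tibble `ks_statistic`, `p_value`.
#' @export
compare_site_distributions <- function(positions_a, positions_b) {
  if (length(positions_a) == 0 || length(positions_b) == 0) {
    rlang::abort("both samples must be non-empty")
  }
  kt <- suppressWarnings(ks.test(positions_a, positions_b, exact = FALSE))
  tibble(ks_statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Length-normalized meta-profile
#'
#' Divides every transcript into `n_bins` equal-width bins along its
#' strand-oriented length, apportions its coverage mass to the bins with
#' fractional-overlap weighting (mass conserving for lengths not divisible
#' by `n_bins`), converts each transcript to bin *fractions* (summing to 1),
#' and sums the fractions across transcripts. Transcripts with zero coverage
#' are excluded from the sum and reported.
#'
#' @param coverage Long tibble `gene_id`, `pos` (0-based genomic),
#'   `coverage`; or a single `crac_pileup`.
#' @param annotations Gene annotation tibble.
#' @param n_bins Number of bins (default 1000).
#' @return A list of class `meta_profile`: `per_transcript` (tibble
#'   `gene_id`, `bin`, `fraction`), `summed` (tibble `bin`, `total`),
#'   `n_transcripts`, `excluded` (zero-coverage gene ids).
#' @export
metaprofile_bins <- function(coverage, annotations, n_bins = 1000) {
  if (inherits(coverage, "crac_pileup")) {
    coverage <- dplyr::mutate(as_tibble(coverage),
                              gene_id = pileup_attr(coverage, "gene_id"))
  }
  check_columns(coverage, c("gene_id", "pos", "coverage"), "coverage")
  annotations <- validate_annotation(as_tibble(annotations))
  stopifnot(n_bins >= 1, all(annotations$length_nt >= 1))
  per <- list()
  excluded <- character(0)
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    cov <- coverage[coverage$gene_id == ann$gene_id, ]
    len <- ann$length_nt
    # strand-oriented transcript coordinate of each covered nucleotide
    u <- genomic_to_rel(cov$pos, ann$tss, ann$strand)
    keep <- u >= 0 & u < len & cov$coverage > 0
    u <- u[keep]
    w <- cov$coverage[keep]
    total <- sum(w)
    if (total <= 0) {
      excluded <- c(excluded, ann$gene_id)
      next
    }
    # cumulative mass C(x) over transcript coordinate x in [0, len]:
    # piecewise linear with knots at integers
    dens <- numeric(len)
    dens[u + 1] <- w
    cum <- c(0, cumsum(dens))
    edges <- seq(0, len, length.out = n_bins + 1)
    at <- function(x) {
      j <- pmin(floor(x), len - 1)
      cum[j + 1] + (x - j) * dens[j + 1]
    }
    mass <- diff(at(edges))
    per[[ann$gene_id]] <- tibble(
      gene_id = ann$gene_id, bin = seq_len(n_bins) - 1L,
      fraction = mass / total
    )
  }
  if (length(excluded) > 0) {
    rlang::inform(paste0("metaprofile_bins: excluded ", length(excluded),
                         " zero-coverage transcript(s)"))
  }
  per_transcript <- dplyr::bind_rows(per)
  summed <- if (nrow(per_transcript) > 0) {
    per_transcript |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(total = sum(.data$fraction), .groups = "drop")
  } else tibble(bin = integer(0), total = numeric(0))
  structure(
    list(per_transcript = per_transcript, summed = summed,
         n_transcripts = length(per), excluded = excluded),
    class = "meta_profile"
  )
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("<meta_profile> %d transcript(s), %d bins, %d excluded\n",
              x$n_transcripts,
              max(0, nrow(x$summed)), length(x$excluded)))
  invisible(x)
}
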