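# ggplot2 helpers for the main result types.

#' Plot normalized binding time courses
#'
#' One panel per transcript, one line per (condition, replicate); the y-axis
#' is whatever scale the input carries (linear relative binding or log2
#' fold-change).
#'
#' @param ntc Normalized long tibble.
#' @param genes Optional subset of gene ids (default: first 9).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(ntc, genes = NULL) {
  validate_timecourse(ntc)
  genes <- genes %||% utils::head(unique(ntc$gene_id), 9)
  d <- dplyr::filter(ntc, .data$gene_id %in% genes)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$timepoint, y = .data$value, colour = .data$condition,
    group = interaction(.data$condition, .data$replicate)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene_id), scales = "free_y") +
    ggplot2::labs(x = "time after shift (min)",
                  y = paste0("relative binding (",
                             timecourse_scale(ntc), ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn kmeans_cluster Plot cluster profiles with centroids.
#' @param object A `kincrac_kmeans` object (autoplot method).
#' @param profiles_data The `profile_set` the clustering was run on, to draw
#'   the per-gene profiles behind the centroids (optional).
#' @export
autoplot.kincrac_kmeans <- function(object, profiles_data = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(profiles_data)) {
    d <- dplyr::left_join(
      dplyr::select(as_tibble(profiles_data), "gene_id", "timepoint",
                    "profile"),
      object$assignments, by = "gene_id"
    )
    p <- p + ggplot2::geom_line(
      data = d,
      ggplot2::aes(x = .data$timepoint, y = .data$profile,
                   group = .data$gene_id),
      colour = "grey70", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_line(
      data = object$centroids,
      ggplot2::aes(x = .data$timepoint, y = .data$profile),
      colour = "black", linewidth = 1
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cluster),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time after shift (min)",
                  y = "log2 fold-change vs t = 0") +
    ggplot2::theme_minimal()
}

#' @describeIn metaprofile_bins Plot the summed length-normalized profile.
#' @param object A `meta_profile` (autoplot method).
#' @param ... Unused.
#' @export
autoplot.meta_profile <- function(object, ...) {
  ggplot2::ggplot(object$summed,
                  ggplot2::aes(x = .data$bin, y = .data$total)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "transcript position (bin)",
                  y = "summed read fraction") +
    ggplot2::theme_minimal()
}

#' Plot a TSS-centered binding-site distribution
#'
#' @param dist Output of [tss_site_distribution()] (optionally several,
#'   bound with an extra `sample` column).
#' @return A ggplot object.
#' @export
plot_tss_distribution <- function(dist) {
  aes <- if ("sample" %in% names(dist)) {
    ggplot2::aes(x = .data$rel_pos, y = .data$frequency,
                 colour = .data$sample)
  } else {
    ggplot2::aes(x = .data$rel_pos, y = .data$frequency)
  }
  ggplot2::ggplot(dist, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to TSS (nt)",
                  y = "summed site frequency", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
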