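# Two-step time-course normalization: (1) constant-factor scaling so that the
# FPKM sum of every (condition, replicate, timepoint) column is the same;
# (2) division of each replicate series by its own pre-stress baseline
# (t = 0), so every surviving series starts at 1 a.u. (0 in log2).

#' Equalize per-timepoint FPKM sums
#'
#' Scales every (condition, replicate, timepoint) column of a time-course
#' matrix by a constant so that all column sums are equal. The default target
#' is the mean of the observed column sums; any positive number can be given
#' instead. Within-column transcript ratios are preserved exactly.
#'
#' @param tc Long time-course tibble (`gene_id`, `condition`, `replicate`,
#'   `timepoint`, `value`).
#' @param target `"auto"` (mean of observed column sums) or a positive number.
#' @return The scaled tibble, with the per-column scaling factors in the
#'   `"factors"` attribute.
#' @export
scale_timepoints <- function(tc, target = "auto") {
  validate_timecourse(tc)
  sums <- tc |>
    dplyr::group_by(.data$condition, .data$replicate, .data$timepoint) |>
    dplyr::summarise(col_sum = sum(.data$value), .groups = "drop")
  if (any(sums$col_sum <= 0)) {
    bad <- sums[sums$col_sum <= 0, ][1, ]
    rlang::abort(sprintf(
      "column (%s, replicate %s, t = %s) has non-positive sum",
      bad$condition, bad$replicate, bad$timepoint
    ))
  }
  tgt <- if (identical(target, "auto")) mean(sums$col_sum) else {
    if (!is_scalar_number(target) || target <= 0) {
      rlang::abort("target must be \"auto\" or a positive number")
    }
    target
  }
  sums$factor <- tgt / sums$col_sum
  out <- tc |>
    dplyr::left_join(sums, by = c("condition", "replicate", "timepoint")) |>
    dplyr::mutate(value = .data$value * .data$factor) |>
    dplyr::select(-"col_sum", -"factor")
  attr(out, "factors") <- sums
  set_timecourse_scale(out, "fpkm")
}

#' Normalize each series to its pre-stress baseline
#'
#' Divides every (transcript, condition, replicate) time series by its own
#' value at t = 0, so all series start at the same relative binding value of
#' 1 a.u. and later values are relative to the pre-shift signal. Transcripts
#' whose normalized series contains any non-finite value (e.g. a zero
#' baseline) are dropped and reported; only complete series are kept.
#'
#' @param tc Long time-course tibble whose timepoint grid includes 0.
#' @param quiet Suppress the drop report message.
#' @return A normalized tibble (attribute `scale = "linear"`); dropped gene
#'   ids are in the `"dropped"` attribute.
#' @export
relative_to_baseline <- function(tc, quiet = FALSE) {
  validate_timecourse(tc)
  if (!0 %in% tc$timepoint) {
    rlang::abort("timepoint grid must include t = 0")
  }
  out <- tc |>
    dplyr::group_by(.data$gene_id, .data$condition, .data$replicate) |>
    dplyr::mutate(value = .data$value /
                    .data$value[.data$timepoint == 0][1]) |>
    dplyr::ungroup()
  bad <- unique(out$gene_id[!is.finite(out$value)])
  out <- dplyr::filter(out, !.data$gene_id %in% bad)
  if (!quiet && length(bad) > 0) {
    rlang::inform(paste0("relative_to_baseline: dropped ", length(bad),
                         " transcript(s) with non-finite values"))
  }
  attr(out, "dropped") <- bad
  set_timecourse_scale(out, "linear")
}

#' Convert a baseline-normalized series to log2
#'
#' Replaces linear relative-binding values by their log2, so that t = 0 is
#' exactly 0 and later values are log2 fold-changes relative to the pre-shift
#' sample.
#'
#' @param ntc A linear-scale normalized tibble from [relative_to_baseline()].
#' @return The log2 tibble (attribute `scale = "log2"`).
#' @export
to_log2 <- function(ntc) {
  validate_timecourse(ntc)
  if (identical(timecourse_scale(ntc), "log2")) return(ntc)
  if (any(ntc$value <= 0)) {
    bad <- unique(ntc$gene_id[ntc$value <= 0])
    rlang::abort(paste0("non-positive value(s) for transcript(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  ntc$value <- log2(ntc$value)
  set_timecourse_scale(ntc, "log2")
}
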