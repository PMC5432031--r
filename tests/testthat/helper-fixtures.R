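# Shared in-code fixtures and independent oracles.

# Naive dense-inverse multivariate-normal log density: the independent
# oracle for the GP evidence (explicit inverse + log-determinant, no
# Cholesky path shared with the implementation).
naive_mvn_logdensity <- function(times, values, hyper) {
  K <- hyper$alpha_sq *
    exp(-outer(times, times, "-")^2 / (2 * hyper$lengthscale_min^2))
  C <- K + diag(hyper$noise_sq, length(values))
  Ci <- solve(C)
  ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  as.numeric(-0.5 * t(values) %*% Ci %*% values - 0.5 * ld -
               length(values) / 2 * log(2 * pi))
}

# Long observation tibble on the standard grid for one transcript.
make_obs <- function(control, treated, tp = c(0, 1, 2, 4, 8, 14, 20),
                     n_rep = nrow(control)) {
  # control/treated: matrices replicates x timepoints
  dplyr::bind_rows(
    purrr::map_dfr(seq_len(nrow(control)), function(r)
      tibble::tibble(condition = "control", replicate = r, timepoint = tp,
                     value = control[r, ])),
    purrr::map_dfr(seq_len(nrow(treated)), function(r)
      tibble::tibble(condition = "treated", replicate = r, timepoint = tp,
                     value = treated[r, ]))
  )
}

# Small long time-course tibble from a genes x timepoints value matrix,
# replicated identically unless noise is added by the caller.
make_timecourse <- function(values, tp = c(0, 4, 8),
                            conditions = "control", replicates = 1) {
  genes <- rownames(values) %||% paste0("g", seq_len(nrow(values)))
  grid <- tidyr::crossing(gene_id = genes, condition = conditions,
                          replicate = replicates)
  purrr::pmap_dfr(grid, function(gene_id, condition, replicate) {
    row <- as.numeric(values[match(gene_id, genes), ])
    tibble::tibble(
      gene_id = gene_id, condition = condition, replicate = replicate,
      timepoint = tp, value = row
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force per-base interval stabbing oracle for pileups.
brute_coverage <- function(starts, ends, region_start, region_end) {
  vapply(seq(region_start, region_end - 1), function(p)
    sum(starts <= p & ends > p), numeric(1))
}

# Brute-force maximal-interval scan oracle for peak calling (height mode).
brute_peaks <- function(cov, min_reads, min_width) {
  above <- cov >= min_reads & cov > 0
  res <- list()
  i <- 1
  while (i <= length(cov)) {
    if (above[i]) {
      j <- i
      while (j < length(cov) && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_width) {
        res[[length(res) + 1]] <- c(start = i - 1, end = j)
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (length(res) == 0) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  m <- do.call(rbind, res)
  tibble::tibble(start = unname(m[, "start"]), end = unname(m[, "end"]))
}
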