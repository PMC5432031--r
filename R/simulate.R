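# Seeded synthetic-data generators. simulate_timecourse() emulates the
# experimental design of a two-condition kinetic CRAC time course (control
# shift vs stress shift, 2 biological replicates, minute-scale grid) with
# GP-smooth latent binding dynamics on the log2 scale, transcript-specific
# baseline abundances and iid Gaussian observation noise, emitted as raw
# FPKM-like values. simulate_gene_reads() builds toy gene read sets with
# 5'-proximal binding peaks, PCR duplicates, multimappers and planted
# non-encoded oligo(A) tails, together with the ground truth for every
# downstream detector.

#' Simulation design for a two-condition binding time course
#'
#' Captures the generative design the differential-dynamics test assumes:
#' latent log2 binding responses drawn from a zero-mean GP with a
#' squared-exponential kernel on the shared timepoint grid; under H0 one
#' latent shared by both conditions, under H1 independent latents with the
#' treated one offset by `effect_size` at every t > 0; iid Gaussian noise
#' (sd `sigma`) on the log2 scale; transcript baseline abundances log-normal
#' across transcripts. Defaults mirror a minute-scale glucose-shift design:
#' grid \{0, 1, 2, 4, 8, 14, 20\} min and 2 replicates per condition.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param hypothesis `"H0"` (shared dynamics) or `"H1"` (condition-specific).
#' @param timepoints Sampling grid in minutes (ascending, first = 0).
#' @param n_replicates Replicates per condition.
#' @param alpha_sq Latent signal variance on the log2 scale (a.u.^2).
#' @param lengthscale_min Latent lengthscale (minutes).
#' @param sigma Observation noise sd on the log2 scale (> 0).
#' @param effect_size H1 treated-condition offset at t > 0 (log2 a.u.).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of transcript
#'   log2 baseline abundances (FPKM mimicry).
#' @param seed Integer seed (mandatory).
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_transcripts = 100, hypothesis = c("H0", "H1"),
                     timepoints = c(0, 1, 2, 4, 8, 14, 20),
                     n_replicates = 2, alpha_sq = 0.04,
                     lengthscale_min = 2, sigma = 0.1, effect_size = 1,
                     baseline_log2_mean = 5, baseline_log2_sd = 2,
                     seed = NULL) {
  hypothesis <- match.arg(hypothesis)
  if (is.null(seed)) rlang::abort("sim_spec() requires an explicit seed")
  if (!is_scalar_number(sigma) || sigma <= 0) {
    rlang::abort("sigma must be positive")
  }
  stopifnot(timepoints[1] == 0, !is.unsorted(timepoints, strictly = TRUE),
            n_transcripts >= 1, n_replicates >= 1,
            alpha_sq > 0, lengthscale_min > 0)
  structure(
    list(n_transcripts = n_transcripts, hypothesis = hypothesis,
         timepoints = timepoints, n_replicates = n_replicates,
         alpha_sq = alpha_sq, lengthscale_min = lengthscale_min,
         sigma = sigma, effect_size = effect_size,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# One latent draw from the zero-mean GP at the design's timepoints.
draw_latent <- function(spec) {
  K <- se_kernel_matrix(spec$timepoints,
                        gp_hyperparams(spec$alpha_sq, spec$lengthscale_min,
                                       .kincrac_var_floor))
  L <- chol_jitter(K)
  drop(t(L) %*% rnorm(length(spec$timepoints)))
}

#' Simulate a two-condition binding time course
#'
#' Draws FPKM-like series for `n_transcripts` transcripts under the design in
#' `spec` (see [sim_spec()]) and returns both the raw time-course table and
#' the per-transcript truth labels. Output values are
#' `2^(baseline + latent + noise)`, so every series is positive at t = 0 and
#' the full normalization + GP-test pipeline applies unchanged.
#'
#' @param spec A [sim_spec()].
#' @return A list with `timecourse` (long tibble: `gene_id`, `condition`,
#'   `replicate`, `timepoint`, `value`) and `truth` (tibble: `gene_id`,
#'   `hypothesis`, `differential`).
#' @examples
#' sim <- simulate_timecourse(sim_spec(n_transcripts = 5, seed = 1))
#' head(sim$timecourse)
#' @export
simulate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  tp <- spec$timepoints
  conds <- c("control", "treated")
  with_seed(spec$seed, {
    rows <- lapply(seq_len(spec$n_transcripts), function(i) {
      gene <- sprintf("gene_%04d", i)
      base <- rnorm(1, spec$baseline_log2_mean, spec$baseline_log2_sd)
      if (spec$hypothesis == "H0") {
        shared <- draw_latent(spec)
        latent <- list(control = shared, treated = shared)
      } else {
        latent <- list(
          control = draw_latent(spec),
          treated = draw_latent(spec) + spec$effect_size * as.numeric(tp > 0)
        )
      }
      grid <- tidyr::crossing(
        condition = conds, replicate = seq_len(spec$n_replicates),
        timepoint = tp
      )
      f <- purrr::map2_dbl(grid$condition, match(grid$timepoint, tp),
                           function(cond, j) latent[[cond]][j])
      tibble(
        gene_id = gene, condition = grid$condition,
        replicate = grid$replicate, timepoint = grid$timepoint,
        value = 2^(base + f + rnorm(nrow(grid), 0, spec$sigma))
      )
    })
    tc <- dplyr::bind_rows(rows)
    truth <- tibble(
      gene_id = sprintf("gene_%04d", seq_len(spec$n_transcripts)),
      hypothesis = spec$hypothesis,
      differential = spec$hypothesis == "H1"
    )
    list(timecourse = set_timecourse_scale(tc, "fpkm"), truth = truth)
  })
}

# Random nucleotide string without any A-run of length >= 3 (so planted
# A-runs are the only encoded decoys in a simulated genome).
random_sequence_no_arun <- function(n) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (n >= 3) {
    repeat {
      runs <- rle(s)
      bad <- which(runs$values == "A" & runs$lengths >= 3)
      if (length(bad) == 0) break
      ends <- cumsum(runs$lengths)
      for (b in bad) s[ends[b]] <- sample(c("C", "G", "T"), 1)
    }
  }
  paste(s, collapse = "")
}

#' Simulate a toy gene read set with known truth
#'
#' Generates aligned reads for one annotated gene: background reads uniform
#' over the gene, binding-site reads Poisson-distributed around specified
#' peak rates, a fraction of reads carrying planted non-encoded oligo(A)
#' tails (with optional genomic A-run decoys that make a tail *encoded*),
#' PCR duplicates sharing `(umi, sequence)`, and multimappers with extra
#' decoy alignments. A synthetic reference genome for the gene's contig is
#' returned alongside the truth objects, so every downstream detector
#' (duplicate collapsing, peak calling, oligo-A detection) can be scored.
#'
#' @param annotation One-row gene annotation (see [gene_annotation()]).
#' @param peaks Data frame with columns `position` (peak start, nt from the
#'   TSS), `width` (nt) and `rate` (expected read count); all peaks must lie
#'   inside the gene.
#' @param n_background Expected number of uniform background reads.
#' @param oligoa_fraction Fraction of reads carrying a planted oligo(A) tail.
#' @param decoy_fraction Fraction of *tailed* reads whose downstream genomic
#'   sequence is an A-run of the same length (encoded tails, which
#'   [detect_oligoA()] must suppress).
#' @param duplicate_rate Fraction of reads re-emitted as PCR duplicates.
#' @param multimap_rate Fraction of reads given one extra decoy alignment.
#' @param read_length Read length in nt.
#' @param min_tail,max_tail Planted tail length range (nt).
#' @param umi_length Random-barcode length (nt).
#' @param seed Integer seed (mandatory).
#' @return A list with `reads` (read table), `genome` (named character vector
#'   of contig sequences) and `truth` (list: `peaks`, `tails`,
#'   `duplicate_of`, `n_molecules`).
#' @export
simulate_gene_reads <- function(annotation, peaks = NULL, n_background = 50,
                                oligoa_fraction = 0, decoy_fraction = 0,
                                duplicate_rate = 0, multimap_rate = 0,
                                read_length = 40, min_tail = 3, max_tail = 8,
                                umi_length = 6, seed) {
  annotation <- validate_annotation(as_tibble(annotation))[1, ]
  stopifnot(all(c(oligoa_fraction, decoy_fraction, duplicate_rate,
                  multimap_rate) >= 0),
            all(c(oligoa_fraction, decoy_fraction, duplicate_rate,
                  multimap_rate) <= 1))
  len <- annotation$length_nt
  span <- gene_span(annotation)
  if (!is.null(peaks)) {
    check_columns(peaks, c("position", "width", "rate"), "peaks")
    if (any(peaks$position < 0 | peaks$position + peaks$width > len)) {
      rlang::abort("peak outside gene")
    }
  }
  with_seed(seed, {
    # molecule 5' positions in transcript coordinates [0, len)
    starts_t <- numeric(0)
    if (n_background > 0) {
      nb <- rpois(1, n_background)
      starts_t <- c(starts_t, floor(runif(nb, 0, max(1, len - read_length))))
    }
    if (!is.null(peaks)) {
      for (i in seq_len(nrow(peaks))) {
        np <- rpois(1, peaks$rate[i])
        lo <- max(0, peaks$position[i] - read_length + 1)
        hi <- max(lo + 1, peaks$position[i] + peaks$width[i] - 1)
        starts_t <- c(starts_t, floor(runif(np, lo, min(hi, len - 1))))
      }
    }
    n_mol <- length(starts_t)
    if (n_mol == 0L) {
      genome <- setNames(random_sequence_no_arun(span[["end"]] + 200),
                         annotation$chrom)
      return(list(
        reads = read_table(character(0)), genome = genome,
        truth = list(peaks = peaks, tails = tibble(), duplicate_of = tibble(),
                     n_molecules = 0L)
      ))
    }
    ends_t <- pmin(starts_t + read_length, len)
    # transcript -> genomic (strand-aware, half-open both ways)
    if (annotation$strand == "+") {
      g_start <- annotation$tss + starts_t
      g_end <- annotation$tss + ends_t
    } else {
      g_start <- annotation$tss - ends_t + 1
      g_end <- annotation$tss - starts_t + 1
    }
    ids <- sprintf("mol_%05d", seq_len(n_mol))
    reads <- read_table(
      read_id = ids,
      sequence = vapply(seq_len(n_mol), function(i)
        paste(sample(c("A", "C", "G", "T"), ends_t[i] - starts_t[i],
                     replace = TRUE), collapse = ""), character(1)),
      umi = vapply(seq_len(n_mol), function(i)
        paste(sample(c("A", "C", "G", "T"), umi_length, replace = TRUE),
              collapse = ""), character(1)),
      chrom = annotation$chrom, start = g_start, end = g_end,
      strand = annotation$strand
    )
    # plant oligo-A tails (soft-clipped, as-sequenced = transcribed strand)
    tailed <- which(runif(n_mol) < oligoa_fraction)
    tail_len <- integer(0)
    decoy <- logical(0)
    if (length(tailed) > 0) {
      tail_len <- sample(seq(min_tail, max_tail), length(tailed),
                         replace = TRUE)
      decoy <- runif(length(tailed)) < decoy_fraction
      reads$soft_clip3[tailed] <- strrep("A", tail_len)
    }
    # synthetic contig, free of accidental A-runs, then plant decoy runs
    genome_len <- span[["end"]] + 200
    gseq <- strsplit(random_sequence_no_arun(genome_len), "")[[1]]
    if (any(decoy)) {
      for (k in which(decoy)) {
        i <- tailed[k]
        tl <- tail_len[k]
        if (annotation$strand == "+") {
          idx <- (reads$end[i] + 1):(reads$end[i] + tl)  # 1-based slice
          gseq[idx] <- "A"
        } else {
          idx <- (reads$start[i] - tl):(reads$start[i] - 1) + 1
          idx <- idx[idx >= 1]
          gseq[idx] <- "T"   # A on the transcribed (minus) strand
        }
      }
    }
    genome <- setNames(paste(gseq, collapse = ""), annotation$chrom)
    # encodedness is a property of the final genome: a decoy run planted for
    # one read can also sit downstream of another tailed read's end
    truth_tails <- if (length(tailed) > 0) {
      encoded <- vapply(seq_along(tailed), function(k) {
        i <- tailed[k]
        tl <- tail_len[k]
        if (annotation$strand == "+") {
          down <- substr(genome[[1]], reads$end[i] + 1, reads$end[i] + tl)
          down == strrep("A", tl)
        } else {
          down <- substr(genome[[1]], max(1, reads$start[i] - tl + 1),
                         reads$start[i])
          down == strrep("T", tl)
        }
      }, logical(1))
      tibble(
        read_id = ids[tailed], tail_len = tail_len, encoded = encoded,
        genomic_end = ifelse(rep(annotation$strand == "+", length(tailed)),
                             reads$end[tailed] - 1, reads$start[tailed])
      )
    } else tibble()
    # PCR duplicates: re-emit rows sharing (umi, sequence)
    dup_of <- which(runif(n_mol) < duplicate_rate)
    if (length(dup_of) > 0) {
      dups <- reads[dup_of, , drop = FALSE]
      dups$read_id <- paste0(dups$read_id, "_dup")
      reads <- dplyr::bind_rows(reads, dups)
    }
    # multimappers: one extra decoy alignment on a decoy contig
    mm <- which(runif(nrow(reads)) < multimap_rate)
    if (length(mm) > 0) {
      extra <- reads[mm, , drop = FALSE]
      extra$chrom <- "chr_decoy"
      extra$start <- floor(runif(length(mm), 0, 5000))
      extra$end <- extra$start + (extra$end - extra$start)
      reads <- dplyr::bind_rows(reads, extra)
      genome <- c(genome, chr_decoy = random_sequence_no_arun(
        5000 + read_length + max_tail + 10))
    }
    list(
      reads = reads, genome = genome,
      truth = list(
        peaks = peaks, tails = truth_tails,
        duplicate_of = tibble(read_id = paste0(ids[dup_of], "_dup"),
                              original = ids[dup_of]),
        n_molecules = n_mol
      )
    )
  })
}
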