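# Profile filtering, K-means, TSS alignment, site distributions and
# meta-profile binning.

make_profile_ntc <- function(mat_r1, mat_r2, tp) {
  # two replicate matrices (genes x timepoints) of linear relative values
  genes <- rownames(mat_r1)
  out <- dplyr::bind_rows(
    purrr::map_dfr(seq_along(genes), function(i)
      tibble::tibble(gene_id = genes[i], condition = "treated",
                     replicate = 1, timepoint = tp, value = mat_r1[i, ])),
    purrr::map_dfr(seq_along(genes), function(i)
      tibble::tibble(gene_id = genes[i], condition = "treated",
                     replicate = 2, timepoint = tp, value = mat_r2[i, ]))
  )
  attr(out, "scale") <- "linear"
  out
}

test_that("filter_profiles applies fold and correlation thresholds", {
  tp <- c(0, 4, 8)
  flat <- c(1, 1.4, 1.2)      # max fold 1.4 -> excluded
  up <- c(1, 2, 3)            # fold 3, replicates agree -> kept
  down <- c(1, 0.5, 0.4)      # fold 2.5 downward counts as fold >= 1.5
  noisy1 <- c(1, 3, 0.5)      # strong fold but replicates disagree
  noisy2 <- c(1, 0.4, 2.8)
  r1 <- rbind(flat, up, down, noisy1)
  r2 <- rbind(flat, up, down, noisy2)
  rownames(r1) <- rownames(r2) <- c("flat", "up", "down", "noisy")
  ps <- filter_profiles(make_profile_ntc(r1, r2, tp))
  expect_setequal(unique(ps$gene_id), c("up", "down"))
  stats <- attr(ps, "stats")
  expect_equal(stats$max_fold[stats$gene_id == "flat"], 1.4)
  expect_lt(stats$replicate_cor[stats$gene_id == "noisy"], 0.7)
  # replicate-averaged log2 profile emitted
  expect_equal(ps$profile[ps$gene_id == "up" & ps$timepoint == 4], 1)
  # boundary: correlation 0.65 excluded, fold exactly 1.5 passes
  exact <- rbind(x = c(1, 1.5, 1))
  ps2 <- filter_profiles(make_profile_ntc(exact, exact, tp))
  expect_equal(unique(ps2$gene_id), "x")
  # 20-transcript fixture equals brute-force rule application
  set.seed(77)
  m1 <- matrix(rexp(20 * 3, 1) + 0.2, 20, 3,
               dimnames = list(paste0("g", 1:20), NULL))
  m1[, 1] <- 1
  m2 <- m1 * matrix(runif(60, 0.6, 1.6), 20, 3)
  m2[, 1] <- 1
  got <- unique(filter_profiles(make_profile_ntc(m1, m2, tp))$gene_id)
  brute <- vapply(1:20, function(i) {
    avg <- (m1[i, ] + m2[i, ]) / 2
    fold <- max(pmax(avg, 1 / avg))
    fold >= 1.5 && cor(m1[i, ], m2[i, ]) >= 0.7
  }, logical(1))
  expect_setequal(got, paste0("g", which(brute)))
  # filtering is idempotent on the retained set
  # (re-deriving from the kept transcripts keeps them all)
  kept_ntc <- make_profile_ntc(m1[brute, , drop = FALSE],
                               m2[brute, , drop = FALSE], tp)
  expect_setequal(unique(filter_profiles(kept_ntc)$gene_id), got)
})

test_that("filter_profiles requires replicates for the correlation rule", {
  tp <- c(0, 4)
  one_rep <- tibble::tibble(gene_id = "g", condition = "treated",
                            replicate = 1, timepoint = tp, value = c(1, 2))
  expect_error(filter_profiles(one_rep), "replicate")
})

test_that("kmeans recovers separable groups and is seed-reproducible", {
  tp <- c(0, 1, 2, 4)
  set.seed(3)
  up <- purrr::map_dfr(1:10, function(i)
    tibble::tibble(gene_id = paste0("up", i), timepoint = tp,
                   profile = c(0, 1, 2, 3) + rnorm(4, 0, 0.05)))
  dn <- purrr::map_dfr(1:10, function(i)
    tibble::tibble(gene_id = paste0("dn", i), timepoint = tp,
                   profile = c(0, -1, -2, -3) + rnorm(4, 0, 0.05)))
  prof <- dplyr::bind_rows(up, dn)
  fit <- kmeans_cluster(prof, k = 2, seed = 11)
  asg <- tidy(fit)
  # perfect partition (adjusted Rand index 1 <=> groups align exactly)
  truth <- grepl("^up", asg$gene_id)
  tab <- table(truth, asg$cluster)
  expect_equal(sort(apply(tab, 1, max)), sort(rowSums(tab)))
  # reproducibility
  fit2 <- kmeans_cluster(prof, k = 2, seed = 11)
  expect_equal(tidy(fit2), asg)
  expect_equal(glance(fit2)$inertia, glance(fit)$inertia)
  # k = 1: single cluster, centroid = mean profile
  f1 <- kmeans_cluster(prof, k = 1, seed = 4)
  expect_equal(unique(tidy(f1)$cluster), 0L)
  mean_prof <- prof |>
    dplyr::group_by(timepoint) |>
    dplyr::summarise(m = mean(profile))
  expect_equal(dplyr::arrange(f1$centroids, timepoint)$profile,
               mean_prof$m, tolerance = 1e-10)
  # duplication invariance: duplicating transcripts doubles cluster sizes
  dup <- dplyr::mutate(prof, gene_id = paste0(gene_id, "_copy"))
  fitd <- kmeans_cluster(dplyr::bind_rows(prof, dup), k = 2, seed = 11)
  expect_equal(sort(unname(table(tidy(fitd)$cluster))),
               2 * sort(unname(table(asg$cluster))))
  expect_error(kmeans_cluster(prof, k = 0, seed = 1), "k must")
  expect_error(kmeans_cluster(prof, k = 21, seed = 1), "k must")
})

test_that("tss_aligned_matrix maps strand-aware relative coordinates", {
  ann <- dplyr::bind_rows(
    gene_annotation("plus", "chr1", "+", tss = 100, end3 = 300),
    gene_annotation("minus", "chr1", "-", tss = 100, end3 = 20)
  )
  cov <- dplyr::bind_rows(
    tibble::tibble(gene_id = "plus", pos = 40:310,
                   coverage = as.numeric(40:310)),
    tibble::tibble(gene_id = "minus", pos = 21:150,
                   coverage = as.numeric(21:150))
  )
  m <- tss_aligned_matrix(cov, ann, window = 50)
  plus <- dplyr::filter(m, gene_id == "plus")
  # + strand: relative -50 maps to genomic 50
  expect_equal(plus$value[plus$rel_pos == -50], 50)
  expect_equal(plus$value[plus$rel_pos == 0], 100)
  # - strand: relative +10 maps to genomic 90
  minus <- dplyr::filter(m, gene_id == "minus")
  expect_equal(minus$value[minus$rel_pos == 10], 90)
  # round trip: relative -> genomic -> relative is the identity
  expect_equal(minus$value[minus$rel_pos == -25], 125)
  # rows sorted by length (minus: 80 nt < plus: 200 nt)
  expect_equal(unique(m$gene_id), c("minus", "plus"))
  # missing coverage is NA, not zero
  sparse <- tss_aligned_matrix(
    tibble::tibble(gene_id = "plus", pos = 100, coverage = 7),
    ann[1, ], window = 2)
  expect_true(is.na(sparse$value[sparse$rel_pos == 2]))
  # flat field: uniform coverage gives equal non-missing cells
  flat <- tss_aligned_matrix(
    tibble::tibble(gene_id = "plus", pos = 90:110, coverage = 3),
    ann[1, ], window = 5)
  expect_equal(unique(flat$value), 3)
})

test_that("tss_site_distribution normalizes within genes before summing", {
  ann <- dplyr::bind_rows(
    gene_annotation("a", "chr1", "+", tss = 100, end3 = 400),
    gene_annotation("b", "chr1", "+", tss = 500, end3 = 900)
  )
  # all sites exactly at the TSS -> delta at 0
  d0 <- tss_site_distribution(
    tibble::tibble(gene_id = c("a", "b"), pos = c(100, 500)), ann,
    window = 20)
  expect_equal(d0$frequency[d0$rel_pos == 0], 2)
  expect_equal(sum(d0$frequency), 2)
  # one gene with sites at -10 and +10 -> 0.5 mass at each
  d1 <- tss_site_distribution(
    tibble::tibble(gene_id = c("a", "a"), pos = c(90, 110)), ann,
    window = 20)
  expect_equal(d1$frequency[d1$rel_pos %in% c(-10, 10)], c(0.5, 0.5))
  # 3-gene fixture equals a brute-force tally
  sites <- tibble::tibble(gene_id = c("a", "a", "a", "b", "b"),
                          pos = c(95, 95, 105, 510, 520))
  d2 <- tss_site_distribution(sites, ann, window = 25)
  expect_equal(d2$frequency[d2$rel_pos == -5], 2 / 3)
  expect_equal(d2$frequency[d2$rel_pos == 5], 1 / 3)
  expect_equal(d2$frequency[d2$rel_pos == 10], 1 / 2)
  expect_equal(d2$frequency[d2$rel_pos == 20], 1 / 2)
})

test_that("KS comparison matches an exhaustive ECDF sweep", {
  expect_equal(compare_site_distributions(1:5, 1:5)$ks_statistic, 0)
  expect_equal(compare_site_distributions(1:5, 11:15)$ks_statistic, 1)
  a <- c(1, 3, 5, 7, 9); b <- c(2, 3, 8, 10, 12)
  grid <- sort(unique(c(a, b)))
  brute_d <- max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
  expect_equal(compare_site_distributions(a, b)$ks_statistic, brute_d)
  expect_error(compare_site_distributions(numeric(0), 1:3), "non-empty")
})

test_that("metaprofile bins conserve mass with fractional overlap", {
  # uniform coverage, length divisible by bins -> equal fractions
  ann <- gene_annotation("u", "chr1", "+", tss = 0, end3 = 1000)
  cov <- tibble::tibble(gene_id = "u", pos = 0:999, coverage = 2)
  mp <- metaprofile_bins(cov, ann, n_bins = 10)
  expect_equal(mp$per_transcript$fraction, rep(0.1, 10))
  # 5'-confined coverage lands in the first bins
  cov5 <- tibble::tibble(gene_id = "u", pos = 0:999,
                         coverage = c(rep(1, 100), rep(0, 900)))
  mp5 <- metaprofile_bins(cov5, ann, n_bins = 1000)
  expect_equal(sum(mp5$per_transcript$fraction[1:100]), 1)
  expect_equal(sum(mp5$per_transcript$fraction[101:1000]), 0)
  # non-divisible length vs brute-force apportionment
  ann2 <- gene_annotation("w", "chr1", "+", tss = 0, end3 = 7)
  covw <- tibble::tibble(gene_id = "w", pos = 0:6,
                         coverage = c(3, 0, 1, 2, 0, 0, 5))
  mpw <- metaprofile_bins(covw, ann2, n_bins = 3)
  # brute force: bin edges at 0, 7/3, 14/3, 7; nt i spreads uniformly over
  # [i, i+1)
  brute <- numeric(3)
  for (i in 0:6) {
    for (bin in 1:3) {
      lo <- (bin - 1) * 7 / 3; hi <- bin * 7 / 3
      ov <- max(0, min(i + 1, hi) - max(i, lo))
      brute[bin] <- brute[bin] + covw$coverage[i + 1] * ov
    }
  }
  expect_equal(mpw$per_transcript$fraction, brute / sum(brute),
               tolerance = 1e-12)
  expect_equal(sum(mpw$per_transcript$fraction), 1, tolerance = 1e-9)
  # minus-strand orientation: 5' mass must land in early bins
  annm <- gene_annotation("m", "chr1", "-", tss = 99, end3 = -1)
  covm <- tibble::tibble(gene_id = "m", pos = 0:99,
                         coverage = c(rep(0, 90), rep(1, 10)))
  mpm <- metaprofile_bins(covm, annm, n_bins = 10)
  expect_equal(mpm$per_transcript$fraction[1], 1)
  # zero-coverage transcripts excluded and reported; summed profile total
  # equals the number of contributing transcripts
  both <- dplyr::bind_rows(cov, tibble::tibble(gene_id = "w", pos = 0:6,
                                               coverage = 0))
  anns <- dplyr::bind_rows(ann, ann2)
  mpb <- suppressMessages(metaprofile_bins(both, anns, n_bins = 10))
  expect_equal(mpb$excluded, "w")
  expect_equal(sum(mpb$summed$total), 1)
})
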