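# GP evidence, empirical-Bayes rules and the Bayes-factor decision.

test_that("se_covariance matches its closed form", {
  h <- gp_hyperparams(4, 1, 0.1)
  expect_equal(se_covariance(3, 3, h), 4)
  expect_equal(se_covariance(0, 1, gp_hyperparams(1, 1, 0.1)),
               exp(-0.5))
  expect_equal(se_covariance(0, 1, h), se_covariance(1, 0, h))
  # effectively zero far beyond the lengthscale
  expect_lt(se_covariance(0, 100, gp_hyperparams(1, 1, 0.1)), 1e-300)
})

test_that("log marginal likelihood is exact against independent oracles", {
  # univariate: value 0, a2 = 1, s2 = 1 -> -0.5 log(4 pi)
  expect_equal(log_marginal_likelihood(0, 0, gp_hyperparams(1, 1, 1)),
               -0.5 * log(4 * pi))

  # two replicates at one time: hand-evaluated bivariate normal with
  # C = [[a2 + s2, a2], [a2, a2 + s2]]
  a2 <- 1.3; s2 <- 0.4; v <- c(0.7, -0.2)
  C <- matrix(c(a2 + s2, a2, a2, a2 + s2), 2)
  hand <- -0.5 * t(v) %*% solve(C) %*% v - 0.5 * log(det(C)) - log(2 * pi)
  expect_equal(
    log_marginal_likelihood(c(2, 2), v, gp_hyperparams(a2, 1, s2)),
    as.numeric(hand), tolerance = 1e-10
  )

  # random 5-point sets vs naive dense-inverse MVN density
  set.seed(101)
  for (i in 1:25) {
    n <- 5
    times <- sort(runif(n, 0, 20))
    y <- rnorm(n)
    h <- gp_hyperparams(runif(1, 0.1, 3), runif(1, 0.5, 3),
                        runif(1, 0.05, 1))
    expect_equal(log_marginal_likelihood(times, y, h),
                 naive_mvn_logdensity(times, y, h), tolerance = 1e-8)
  }
})

test_that("Monte-Carlo estimate agrees with the closed-form evidence (n = 3)", {
  h <- gp_hyperparams(0.8, 1.5, 0.09)
  times <- c(0, 2, 5)
  y <- c(0.3, -0.5, 0.8)
  exact <- exp(log_marginal_likelihood(times, y, h))
  set.seed(99)
  n_draw <- 2e5
  K <- h$alpha_sq * exp(-outer(times, times, "-")^2 /
                          (2 * h$lengthscale_min^2))
  L <- chol(K + diag(1e-10, 3))
  f <- matrix(rnorm(3 * n_draw), ncol = 3) %*% L
  lik <- dnorm(y[1], f[, 1], sqrt(h$noise_sq)) *
    dnorm(y[2], f[, 2], sqrt(h$noise_sq)) *
    dnorm(y[3], f[, 3], sqrt(h$noise_sq))
  mc <- mean(lik)
  se <- stats::sd(lik) / sqrt(n_draw)
  expect_lt(abs(exact - mc), 3 * se)
})

test_that("empirical-Bayes rules follow the stated definitions", {
  vals <- c(0, 2, 4, 2)                      # population variance 2
  h <- empirical_bayes_hyperparams(vals, vals)
  expect_equal(h$alpha_sq, 1)                # 50% of variance
  expect_equal(h$lengthscale_min, 1)         # global 1 min
  expect_equal(h$noise_sq, 2)                # control variance
  # constant control series: floored noise with a warning
  expect_warning(
    h2 <- empirical_bayes_hyperparams(c(0, 1, 0, 1), c(1, 1, 1)),
    "constant"
  )
  expect_equal(h2$noise_sq, 1e-6)
  expect_error(empirical_bayes_hyperparams(c(1, 2), 1), "at least 2")
})

test_that("Bayes-factor decision respects the threshold of 10", {
  # engineered observations with explicit hyperparameters: the flag flips
  # exactly at log BF = ln 10
  res <- structure(list(log_bf = log(12)), class = "gp_test")
  expect_true(log(12) >= log(10))
  expect_false(log(9) >= log(10))
  # and through the real path: shared dynamics vs strongly separated
  tp <- c(0, 1, 2, 4, 8, 14, 20)
  set.seed(2)
  lat <- c(0, cumsum(rnorm(6, 0, 0.1)))
  noise <- function() rnorm(length(tp), 0, 0.1)
  shared <- make_obs(rbind(lat + noise(), lat + noise()),
                     rbind(lat + noise(), lat + noise()), tp)
  sep <- make_obs(rbind(lat + noise(), lat + noise()),
                  rbind(lat + 5 * (tp > 0) + noise(),
                        lat + 5 * (tp > 0) + noise()), tp)
  r_shared <- test_transcript(shared)
  r_sep <- test_transcript(sep)
  expect_false(r_shared$flagged)
  expect_true(r_sep$flagged)
  # invariant: log_bf = logml_h1 - logml_h0 exactly; bf consistent
  expect_identical(r_sep$log_bf, r_sep$logml_h1 - r_sep$logml_h0)
  expect_equal(r_shared$bf, exp(r_shared$log_bf))
  # H0/H1 evidences match the independent naive oracle on the same stacks
  h <- r_shared$hyper
  expect_equal(r_shared$logml_h0,
               naive_mvn_logdensity(shared$timepoint, shared$value, h),
               tolerance = 1e-8)
  ctrl <- dplyr::filter(shared, condition == "control")
  trt <- dplyr::filter(shared, condition == "treated")
  expect_equal(r_shared$logml_h1,
               naive_mvn_logdensity(ctrl$timepoint, ctrl$value, h) +
                 naive_mvn_logdensity(trt$timepoint, trt$value, h),
               tolerance = 1e-8)
})

test_that("condition-label swap leaves log BF unchanged under explicit hyperparameters", {
  tp <- c(0, 1, 2, 4, 8, 14, 20)
  set.seed(8)
  obs <- make_obs(rbind(rnorm(7), rnorm(7)),
                  rbind(rnorm(7), rnorm(7)), tp)
  h <- gp_hyperparams(1, 1, 0.2)
  swapped <- dplyr::mutate(obs, condition = ifelse(condition == "control",
                                                   "treated", "control"))
  expect_equal(test_transcript(obs, hyper = h)$log_bf,
               test_transcript(swapped, hyper = h)$log_bf,
               tolerance = 1e-10)
  # with auto hyperparameters the control-variance noise rule breaks the
  # symmetry by design
  r1 <- test_transcript(obs)
  r2 <- test_transcript(swapped)
  expect_false(isTRUE(all.equal(r1$hyper$noise_sq, r2$hyper$noise_sq)))
})

test_that("test_transcript validates its inputs", {
  one_cond <- tibble::tibble(timepoint = c(0, 1), value = c(0, 1),
                             condition = "control", replicate = 1)
  expect_error(test_transcript(one_cond), "two conditions")
})

test_that("test_all is a per-transcript map, order-equivariant", {
  sim <- simulate_timecourse(sim_spec(n_transcripts = 4, seed = 5))
  ntc <- relative_to_baseline(sim$timecourse, quiet = TRUE)
  res <- test_all(ntc)
  expect_equal(nrow(res), 4L)
  # batch of one equals the single-transcript path
  g1 <- dplyr::filter(to_log2(ntc), gene_id == "gene_0001")
  single <- tidy(test_transcript(g1, gene_id = "gene_0001"))
  expect_equal(res[res$gene_id == "gene_0001", ]$log_bf, single$log_bf)
  # permuting transcript order permutes results identically
  shuf <- ntc[order(rev(seq_len(nrow(ntc)))), ]
  res2 <- test_all(shuf)
  expect_equal(dplyr::arrange(res2, gene_id), dplyr::arrange(res, gene_id))
  expect_error(test_all(ntc[0, ]), "empty")
})

test_that("adding an identical replicate to both conditions preserves the call", {
  tp <- c(0, 1, 2, 4, 8, 14, 20)
  set.seed(13)
  ctrl <- rbind(rnorm(7, 0, 0.1), rnorm(7, 0, 0.1))
  trt <- ctrl + rep(2 * (tp > 0), each = 2)
  base_obs <- make_obs(ctrl, trt, tp)
  more_obs <- make_obs(rbind(ctrl, ctrl[1, ]), rbind(trt, trt[1, ]), tp)
  h <- gp_hyperparams(1, 1, 0.01)
  r_base <- test_transcript(base_obs, hyper = h)
  r_more <- test_transcript(more_obs, hyper = h)
  expect_true(r_base$flagged)
  expect_true(r_more$flagged)
  expect_gte(r_more$log_bf, r_base$log_bf)
})
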