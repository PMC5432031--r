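# Gaussian-process Bayes-factor test for differential binding dynamics.
#
# The binding response f_j(t) of a transcript in condition j is modeled as a
# smooth latent function with a zero-mean GP prior under a squared-exponential
# covariance cov(f(s), f(t)) = a^2 exp(-(s - t)^2 / (2 lambda^2)).
# Observations y_j(t) are the latent values plus iid Gaussian noise (sd
# sigma). Because everything is Gaussian the latent function integrates out
# exactly, giving the evidence p(y(0), ..., y(T) | a, lambda, sigma) in
# closed form. The test compares
#   H0: one shared latent explains control and treated series, versus
#   H1: each condition has its own latent,
# via the Bayes factor; BF >= 10 (log BF >= ln 10) is treated as strong
# evidence for condition-specific dynamics (Kass & Raftery convention).
# Hyperparameters are set by simple empirical-Bayes rules and shared by both
# hypotheses, so no quantity is fitted separately under H1.

#' Gaussian-process hyperparameters
#'
#' Container for the three hyperparameters of the binding-dynamics model:
#' signal variance `alpha_sq` (a.u.^2), lengthscale `lengthscale_min`
#' (minutes) and observation-noise variance `noise_sq` (a.u.^2).
#'
#' @param alpha_sq Signal variance (> 0).
#' @param lengthscale_min Lengthscale in minutes (> 0).
#' @param noise_sq Noise variance; floored at `1e-6`.
#' @return A list of class `gp_hyperparams`.
#' @export
gp_hyperparams <- function(alpha_sq, lengthscale_min = 1, noise_sq) {
  stopifnot(is_scalar_number(alpha_sq), is_scalar_number(lengthscale_min),
            is_scalar_number(noise_sq))
  if (alpha_sq <= 0 || lengthscale_min <= 0) {
    rlang::abort("alpha_sq and lengthscale_min must be positive")
  }
  structure(
    list(alpha_sq = alpha_sq, lengthscale_min = lengthscale_min,
         noise_sq = max(noise_sq, .kincrac_var_floor)),
    class = "gp_hyperparams"
  )
}

#' Squared-exponential covariance
#'
#' `cov(f(s), f(t)) = alpha_sq * exp(-(s - t)^2 / (2 * lengthscale_min^2))`.
#' Vectorized over `s` and `t`.
#'
#' @param s,t Times in minutes.
#' @param hyper A [gp_hyperparams()] object.
#' @return Covariance value(s).
#' @export
se_covariance <- function(s, t, hyper) {
  hyper$alpha_sq * exp(-(s - t)^2 / (2 * hyper$lengthscale_min^2))
}

se_kernel_matrix <- function(times, hyper) {
  d <- outer(times, times, "-")
  hyper$alpha_sq * exp(-d^2 / (2 * hyper$lengthscale_min^2))
}

# Cholesky with escalating diagonal jitter. Returns the factor or errors.
chol_jitter <- function(C, context = "") {
  jitter <- 0
  repeat {
    L <- tryCatch(chol(C + diag(jitter, nrow(C))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jitter <- if (jitter == 0) .kincrac_jitter_min else jitter * 100
    if (jitter > .kincrac_jitter_max) {
      rlang::abort(paste0(
        "covariance matrix not positive definite after maximum jitter",
        if (nzchar(context)) paste0(" (", context, ")"),
        "; condition estimate ", format(kappa(C, exact = FALSE))
      ))
    }
  }
}

#' Exact GP log marginal likelihood
#'
#' Log evidence of a set of observations of one latent binding function:
#' the log density of the stacked values under a zero-mean multivariate
#' normal with covariance `C = K + noise_sq * I`, where
#' `K[i, j] = se_covariance(time_i, time_j)`. Replicate observations at the
#' same time share the latent value (`K[i, j] = alpha_sq`) but carry
#' independent noise. Computed via a Cholesky factorization with escalating
#' diagonal jitter.
#'
#' @param times Observation times (minutes), one per observation; replicate
#'   observations repeat their time.
#' @param values Observed values (a.u.), same length as `times`.
#' @param hyper A [gp_hyperparams()] object.
#' @param context Optional label used in numerical error messages.
#' @return The log marginal likelihood in nats.
#' @export
log_marginal_likelihood <- function(times, values, hyper, context = "") {
  stopifnot(length(times) == length(values), length(times) >= 1L)
  if (!all(is.finite(values)) || !all(is.finite(times))) {
    rlang::abort("times and values must be finite")
  }
  n <- length(values)
  C <- se_kernel_matrix(times, hyper) + diag(hyper$noise_sq, n)
  L <- chol_jitter(C, context)
  alpha <- backsolve(L, forwardsolve(t(L), values))
  -0.5 * sum(values * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
}

#' Empirical-Bayes hyperparameters for one transcript
#'
#' The data-driven rules fixing the hyperparameters before evidence
#' computation: the signal variance `alpha_sq` is 50% of the (population)
#' variance of all binding values of the transcript, pooled over conditions
#' and replicates; the lengthscale is globally 1 min; the noise variance
#' `noise_sq` is the variance of the transcript's control-condition values
#' (the control shift captures technical and shift-induced variability).
#' Both hypotheses are evaluated with these same values.
#'
#' @param all_values All binding values of the transcript (both conditions,
#'   all replicates and timepoints).
#' @param control_values The control-condition values (>= 2).
#' @return A [gp_hyperparams()] object.
#' @export
empirical_bayes_hyperparams <- function(all_values, control_values) {
  if (length(control_values) < 2L || length(all_values) < 2L) {
    rlang::abort("need at least 2 observations overall and in control")
  }
  alpha_sq <- 0.5 * pvar(all_values)
  noise_sq <- pvar(control_values)
  if (!is.finite(alpha_sq) || alpha_sq <= 0) {
    rlang::warn("degenerate (constant) series; flooring alpha_sq")
    alpha_sq <- .kincrac_var_floor
  }
  if (noise_sq < .kincrac_var_floor) {
    rlang::warn("constant control series; flooring noise variance")
  }
  gp_hyperparams(alpha_sq = alpha_sq, lengthscale_min = 1,
                 noise_sq = noise_sq)
}

#' Test one transcript for differential binding dynamics
#'
#' Computes the Bayes factor between H1 (control and treated series arise
#' from two distinct latent dynamics) and H0 (a single shared latent explains
#' all series). Under H0 all observations enter one evidence computation;
#' under H1 the evidences of the two conditions are computed separately and
#' summed (in log). `flagged` is `TRUE` when `log_bf >= log(bf_threshold)`.
#'
#' @param obs Tibble of observations with columns `timepoint`, `value`,
#'   `condition`, `replicate`. Both conditions must be present with >= 2
#'   timepoints each. The first condition level (or `control` if named so)
#'   is taken as the control.
#' @param hyper A [gp_hyperparams()] object, or `NULL` to apply the
#'   empirical-Bayes rules.
#' @param control Which `condition` value is the control series (used for the
#'   noise-variance rule). Defaults to `"control"` when present, else the
#'   first condition.
#' @param include_t0 Include the t = 0 observations in the likelihood
#'   (default `TRUE`).
#' @param bf_threshold Bayes-factor decision threshold (default 10).
#' @param gene_id Optional label carried into the result.
#' @return An object of class `gp_test`: list with `gene_id`, `logml_h0`,
#'   `logml_h1`, `log_bf`, `bf`, `flagged`, `hyper`, `n_obs`. Use [tidy()] for
#'   a one-row tibble.
#' @examples
#' obs <- tidyr::crossing(condition = c("control", "treated"),
#'                        replicate = 1:2,
#'                        timepoint = c(0, 1, 2, 4, 8, 14, 20))
#' obs$value <- ifelse(obs$condition == "treated" & obs$timepoint > 0, 2, 0) +
#'   rnorm(nrow(obs), sd = 0.1)
#' tidy(test_transcript(obs))
#' @export
test_transcript <- function(obs, hyper = NULL, control = NULL,
                            include_t0 = TRUE, bf_threshold = 10,
                            gene_id = NA_character_) {
  check_columns(obs, c("timepoint", "value", "condition"), "obs")
  conds <- unique(obs$condition)
  if (length(conds) != 2L) {
    rlang::abort("obs must contain exactly two conditions")
  }
  control <- control %||% if ("control" %in% conds) "control" else conds[[1]]
  if (!control %in% conds) rlang::abort("control condition not found in obs")
  if (!include_t0) obs <- dplyr::filter(obs, .data$timepoint != 0)
  per_cond <- split(obs, obs$condition)
  if (any(vapply(per_cond, function(d) length(unique(d$timepoint)),
                 numeric(1)) < 2)) {
    rlang::abort("each condition needs >= 2 timepoints")
  }
  if (is.null(hyper)) {
    hyper <- empirical_bayes_hyperparams(
      all_values = obs$value,
      control_values = obs$value[obs$condition == control]
    )
  }
  ctx <- if (is.na(gene_id)) "" else gene_id
  logml_h0 <- log_marginal_likelihood(obs$timepoint, obs$value, hyper,
                                      context = ctx)
  logml_h1 <- sum(vapply(per_cond, function(d) {
    log_marginal_likelihood(d$timepoint, d$value, hyper, context = ctx)
  }, numeric(1)))
  log_bf <- logml_h1 - logml_h0
  structure(
    list(gene_id = gene_id, logml_h0 = logml_h0, logml_h1 = logml_h1,
         log_bf = log_bf, bf = exp(log_bf),
         flagged = log_bf >= log(bf_threshold), hyper = hyper,
         n_obs = nrow(obs)),
    class = "gp_test"
  )
}

#' @export
print.gp_test <- function(x, ...) {
  cat(sprintf(
    "<gp_test> %s  log BF = %.3f (%s)\n",
    x$gene_id %||% "?", x$log_bf,
    if (x$flagged) "differential dynamics" else "no strong evidence"
  ))
  invisible(x)
}

#' @rdname test_transcript
#' @param x A `gp_test` object.
#' @param ... Unused.
#' @export
tidy.gp_test <- function(x, ...) {
  tibble(
    gene_id = x$gene_id, logml_h0 = x$logml_h0, logml_h1 = x$logml_h1,
    log_bf = x$log_bf, bf = x$bf, flagged = x$flagged,
    alpha_sq = x$hyper$alpha_sq, noise_sq = x$hyper$noise_sq
  )
}

#' @rdname test_transcript
#' @export
glance.gp_test <- function(x, ...) {
  tibble(log_bf = x$log_bf, flagged = x$flagged, n_obs = x$n_obs)
}

#' Run the GP test over every transcript of a normalized time course
#'
#' Batch driver: applies [test_transcript()] independently to each transcript
#' of a baseline-normalized time course. The modeled scale is the log2 of the
#' baseline-normalized ratio (zero prior mean); a linear-scale input is
#' converted on the fly when `scale = "log2"`. Per-transcript failures are
#' reported as warnings and skipped, not fatal.
#'
#' @param ntc Normalized long tibble from [relative_to_baseline()] (or its
#'   [to_log2()] form).
#' @param scale `"log2"` (default) or `"linear"` — the scale on which the GP
#'   operates.
#' @param ... Passed to [test_transcript()] (`hyper`, `control`,
#'   `include_t0`, `bf_threshold`).
#' @return A tibble with one [tidy()] row per tested transcript.
#' @export
test_all <- function(ntc, scale = c("log2", "linear"), ...) {
  scale <- match.arg(scale)
  validate_timecourse(ntc)
  if (nrow(ntc) == 0L) rlang::abort("empty input")
  in_scale <- timecourse_scale(ntc)
  if (scale == "log2" && in_scale != "log2") ntc <- to_log2(ntc)
  if (scale == "linear") {
    if (in_scale == "log2") ntc$value <- 2^ntc$value
    # linear relative binding has constant mean 1; the GP prior is zero-mean
    ntc$value <- ntc$value - 1
  }
  results <- lapply(split(ntc, ntc$gene_id), function(d) {
    tryCatch(
      tidy(test_transcript(d, gene_id = d$gene_id[[1]], ...)),
      error = function(e) {
        rlang::warn(paste0("skipping ", d$gene_id[[1]], ": ",
                           conditionMessage(e)))
        NULL
      }
    )
  })
  out <- dplyr::bind_rows(results)
  if (nrow(out) == 0L) return(out)
  # preserve input transcript order
  out <- out[match(unique(ntc$gene_id), out$gene_id), , drop = FALSE]
  dplyr::filter(out, !is.na(.data$gene_id))
}
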