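# Small internal helpers: seeded evaluation, column checks, variance with
# divisor n (population variance, used by the empirical-Bayes rules).

with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

check_columns <- function(df, cols, what = "input") {
  if (!is.data.frame(df)) {
    rlang::abort(paste0(what, " must be a data frame"))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    rlang::abort(paste0(
      what, " is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Population variance (divisor n, not n - 1).
pvar <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- rlang::`%||%`
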