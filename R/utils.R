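#' @importFrom rlang abort warn .data
#' @importFrom stats lm coef pt predict quantile rpois rnorm rlnorm runif sd setNames
#' @importFrom utils packageVersion
NULL

# nearest-rank empirical quantile (inverse-ECDF); exact on small integer
# fixtures, unlike the default type-7 interpolation
quantile_nearest_rank <- function(x, q) {
  stopifnot(length(x) > 0, q >= 0, q <= 1)
  unname(stats::quantile(x, probs = q, type = 1, names = FALSE))
}

# stable 32-bit seed derived from a master seed and string labels, so each
# replicate gets its own reproducible stream independent of draw order
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), as.character, character(1))
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    for (k in utf8ToInt(p)) h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name),
          class = "soilBONCAT_invalid_parameter")
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number", name),
          class = "soilBONCAT_invalid_parameter")
  }
  invisible(x)
}

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a proportion in [0, 1]", name),
          class = "soilBONCAT_invalid_parameter")
  }
  invisible(x)
}
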