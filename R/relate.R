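#' Regress respiration rate on log-scaled active-cell counts
#'
#' Ordinary least-squares fit of the bulk respiration rate on the base-10
#' logarithm of active cells per gram, per treatment or pooled. Samples with
#' zero active cells are excluded (their log is undefined) with a warning
#' recording how many were dropped.
#'
#' @param rates Respiration rates, umol CO2 per g per h.
#' @param active_counts Active cells per g (same length as `rates`).
#' @param group Label stored with the result (`"all"` for pooled fits).
#' @param log_base Base of the log transform applied to the regressor.
#'   Default 10; the slope scales by `log(b2)/log(b1)` under a base change.
#' @return An object of class `loglinear_fit`: `group`, `slope`,
#'   `intercept`, `r_squared`, `p_slope`, `p_intercept`, `n`, `n_excluded`,
#'   and the underlying `lm` fit in `$model`. Use [confidence_band()] for
#'   the 95% mean-response region.
#' @export
fit_loglinear <- function(rates, active_counts, group = "all", log_base = 10) {
  stopifnot(length(rates) == length(active_counts))
  keep <- is.finite(rates) & is.finite(active_counts) & active_counts > 0
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    warn(sprintf("excluding %d sample(s) with zero or missing active cells from regression '%s'",
                 n_excluded, group))
  }
  x <- log(active_counts[keep], base = log_base)
  y <- rates[keep]
  if (length(y) < 3L) {
    abort("need at least 3 samples with positive active counts",
          class = "soilBONCAT_insufficient_data")
  }
  if (length(unique(x)) < 2L) {
    abort("all log active counts identical: singular design",
          class = "soilBONCAT_singular_design")
  }
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  # suppress summary.lm's perfect-fit warning on noiseless fixtures
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  structure(list(group = group, slope = cf["x", "Estimate"],
                 intercept = cf["(Intercept)", "Estimate"],
                 r_squared = sm$r.squared,
                 p_slope = cf["x", "Pr(>|t|)"],
                 p_intercept = cf["(Intercept)", "Pr(>|t|)"],
                 n = length(y), n_excluded = n_excluded,
                 log_base = log_base, model = fit),
            class = "loglinear_fit")
}

#' 95% confidence band for the mean response of a log-linear fit
#'
#' @param fit A [fit_loglinear()] result.
#' @param active_counts Active-cell counts (per g) at which to evaluate the
#'   band; defaults to an even grid over the fitted range (in log space).
#' @param level Confidence level. Default 0.95.
#' @return A tibble: `active_cells_per_g`, `fit`, `lwr`, `upr`.
#' @export
confidence_band <- function(fit, active_counts = NULL, level = 0.95) {
  stopifnot(inherits(fit, "loglinear_fit"))
  if (is.null(active_counts)) {
    xr <- range(fit$model$model$x)
    xs <- seq(xr[1], xr[2], length.out = 50L)
  } else {
    xs <- log(active_counts, base = fit$log_base)
  }
  pr <- predict(fit$model, newdata = data.frame(x = xs),
                interval = "confidence", level = level)
  tibble::tibble(active_cells_per_g = fit$log_base^xs,
                 fit = unname(pr[, "fit"]), lwr = unname(pr[, "lwr"]),
                 upr = unname(pr[, "upr"]))
}

#' Respiration per active cell
#'
#' Divides bulk respiration by the number of active cells for a replicate.
#' Undefined (flagged, not infinite) when the replicate's corrected active
#' count is zero.
#'
#' @param rate Respiration rate, umol CO2 per g per h (non-negative).
#' @param active Active cells per g.
#' @return A list of class `per_cell_respiration`: `value` (umol CO2 per
#'   active cell per h, `NA` when undefined) and `defined`.
#' @examples
#' respiration_per_active_cell(0.5, 1e6)$value # 5e-7
#' @export
respiration_per_active_cell <- function(rate, active) {
  assert_nonneg(rate, "rate")
  assert_nonneg(active, "active")
  if (active == 0) {
    return(structure(list(value = NA_real_, defined = FALSE),
                     class = "per_cell_respiration"))
  }
  structure(list(value = rate / active, defined = TRUE),
            class = "per_cell_respiration")
}

#' Per-treatment and pooled regression summaries
#'
#' Runs [fit_loglinear()] within each treatment and on all samples pooled,
#' returning a tidy summary row per fit.
#'
#' @param merged Table with columns `treatment`, `respiration_rate` and
#'   `active_cells_per_g` (one row per replicate).
#' @param log_base Passed to [fit_loglinear()].
#' @return A tibble: group, slope, intercept, r_squared, p_slope,
#'   p_intercept, n, n_excluded.
#' @export
relate_respiration <- function(merged, log_base = 10) {
  stopifnot(all(c("treatment", "respiration_rate", "active_cells_per_g") %in%
                  names(merged)))
  groups <- c(split(merged, merged$treatment), list(all = merged))
  purrr::imap_dfr(groups, function(df, g) {
    fit <- tryCatch(
      fit_loglinear(df$respiration_rate, df$active_cells_per_g, group = g,
                    log_base = log_base),
      soilBONCAT_insufficient_data = function(e) NULL,
      soilBONCAT_singular_design = function(e) NULL)
    if (is.null(fit)) return(tibble::tibble())
    tibble::tibble(group = g, slope = fit$slope, intercept = fit$intercept,
                   r_squared = fit$r_squared, p_slope = fit$p_slope,
                   p_intercept = fit$p_intercept, n = fit$n,
                   n_excluded = fit$n_excluded)
  })
}
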