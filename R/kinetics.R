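#' Specific growth rate under an exponential model
#'
#' Treats the change in active-cell counts between two time points as if the
#' population were growing exponentially: `mu = ln(n2/n1) / dt`. Because
#' newly activated dormant cells also raise the count, this is the
#' theoretical maximum growth rate that division alone would have needed.
#'
#' @param n1,n2 Counts (cells per g) at the start and end of the interval;
#'   both must be positive.
#' @param dt Interval length, hours.
#' @return Specific growth rate, per hour.
#' @examples
#' specific_growth_rate(1000, 2000, 1) # ln 2
#' @export
specific_growth_rate <- function(n1, n2, dt) {
  assert_positive(dt, "dt")
  if (!is.finite(n1) || !is.finite(n2) || n1 <= 0 || n2 <= 0) {
    abort("specific growth rate is undefined for non-positive counts",
          class = "soilBONCAT_undefined_rate")
  }
  log(n2 / n1) / dt
}

#' Doubling time required to explain an increase by division alone
#'
#' If every new active cell arose from replication of already-active cells,
#' they would have had to double every `dt * ln 2 / ln(n2/n1)` hours.
#' Values shorter than plausible soil generation times indicate that dormant
#' cells were activating rather than active cells dividing.
#'
#' @inheritParams specific_growth_rate
#' @return Required doubling time, hours.
#' @examples
#' required_doubling_time(1000, 87550, 4) # ~0.62 h
#' @export
required_doubling_time <- function(n1, n2, dt) {
  assert_positive(dt, "dt")
  if (!is.finite(n1) || !is.finite(n2) || n1 <= 0 || n2 <= n1) {
    abort("required doubling time needs n2 > n1 > 0",
          class = "soilBONCAT_no_growth")
  }
  dt * log(2) / log(n2 / n1)
}

#' Hourly proportional increase for a given generation time
#'
#' Converts a generation (doubling) time to the proportional increase per
#' hour of an exponentially growing population: `2^(1/t_gen) - 1`. A
#' 20-minute generation time gives 7.0 (the population grows eightfold each
#' hour); 7.2 h gives 0.101.
#'
#' @param t_gen Generation time, hours.
#' @return Proportional increase per hour.
#' @export
hourly_rate_from_generation_time <- function(t_gen) {
  if (!is.numeric(t_gen) || length(t_gen) == 0 || any(!is.finite(t_gen)) ||
      any(t_gen <= 0)) {
    abort("`t_gen` must be positive", class = "soilBONCAT_invalid_parameter")
  }
  2^(1 / t_gen) - 1
}

#' Reference generation times for context
#'
#' Literature growth-rate anchors used when judging whether an observed
#' increase in active cells could plausibly come from replication: a fast
#' laboratory *Escherichia coli* culture (20 min), an active rhizosphere
#' community (7.2 h) and bulk forest soil (14.1 days).
#'
#' @return A tibble with `label`, `generation_time` (h) and `hourly_rate`
#'   (proportional increase per hour).
#' @export
reference_rates <- function() {
  tg <- c(e_coli_culture = 1 / 3, rhizosphere = 7.2, bulk_forest_soil = 14.1 * 24)
  tibble::tibble(label = names(tg), generation_time = unname(tg),
                 hourly_rate = hourly_rate_from_generation_time(unname(tg)))
}

#' Fraction of an observed increase attributable to replication
#'
#' Supposes the already-active cells at the start of the interval replicated
#' exponentially at a reference generation time and asks what fraction of
#' the observed increase that replication would produce:
#' `(2^(dt / t_gen) - 1) * n1 / (n2 - n1)`. Values far below 1 mean
#' replication cannot explain the increase and dormant-cell activation must
#' dominate.
#'
#' @inheritParams specific_growth_rate
#' @param generation_time Reference generation time, hours.
#' @return Attribution fraction (1 = replication fully explains the
#'   increase).
#' @examples
#' replication_attribution(1000, 87550, 4, 7.2) # ~0.0054
#' @export
replication_attribution <- function(n1, n2, dt, generation_time) {
  assert_positive(dt, "dt")
  assert_positive(generation_time, "generation_time")
  if (!is.finite(n1) || !is.finite(n2) || n1 <= 0 || n2 <= n1) {
    abort("replication attribution needs n2 > n1 > 0",
          class = "soilBONCAT_no_growth")
  }
  (2^(dt / generation_time) - 1) * n1 / (n2 - n1)
}

#' Delta-method standard error of the specific growth rate
#'
#' Propagates the standard errors of the two interval means into the
#' log-ratio rate: `se_mu = sqrt((se1/n1)^2 + (se2/n2)^2) / dt`.
#'
#' @param n1,n2 Interval mean counts.
#' @param se1,se2 Standard errors of those means.
#' @param dt Interval length, hours.
#' @return Standard error of `mu`, per hour.
#' @export
propagate_se_mu <- function(n1, se1, n2, se2, dt) {
  assert_positive(dt, "dt")
  if (n1 <= 0 || n2 <= 0) {
    abort("delta-method SE needs positive means",
          class = "soilBONCAT_undefined_rate")
  }
  sqrt((se1 / n1)^2 + (se2 / n2)^2) / dt
}

#' Classify an interval as activation- or replication-driven
#'
#' An interval is `activation-dominated` when the required doubling time is
#' shorter than the fastest plausible soil generation time (default 0.5 h,
#' the theoretical maximum under optimum soil conditions) or when
#' replication at the reference generation time would account for less than
#' `attribution_cutoff` of the observed increase; `replication-plausible`
#' when the required doubling time is at least the reference generation
#' time; otherwise `indeterminate`. Intervals with no increase are
#' `indeterminate`.
#'
#' @param required_td Required doubling time, hours (`NA` when undefined).
#' @param attribution Replication-attribution fraction at the reference
#'   (`NA` when undefined).
#' @param reference_tgen Reference generation time, hours.
#' @param min_plausible_tgen Fastest plausible generation time in soil,
#'   hours. Default 0.5.
#' @param attribution_cutoff Attribution below which replication is
#'   considered negligible. Default 0.05.
#' @return One of `"activation-dominated"`, `"replication-plausible"`,
#'   `"indeterminate"`.
#' @export
classify_interval <- function(required_td, attribution, reference_tgen,
                              min_plausible_tgen = 0.5,
                              attribution_cutoff = 0.05) {
  if (is.na(required_td) || is.na(attribution)) return("indeterminate")
  if (required_td < min_plausible_tgen || attribution < attribution_cutoff) {
    return("activation-dominated")
  }
  if (required_td >= reference_tgen) return("replication-plausible")
  "indeterminate"
}

#' Interval-wise growth estimates from the counts table
#'
#' For each substrate treatment, takes replicate means (and standard errors)
#' of active cells per gram at each time point and computes, for every pair
#' of consecutive time points: the specific growth rate, the hourly
#' proportional change, the doubling time required if all new active cells
#' arose by division, the replication-attribution fraction at the reference
#' generation time, the propagated SE of the rate, and the interval
#' classification. Intervals whose starting mean is zero (all replicates
#' zeroed) or that show no increase yield `NA` ratio quantities and are
#' flagged, never dropped.
#'
#' @param counts Tidy counts table from [enumerate_samples()] (columns
#'   `treatment`, `time_h`, `active_cells_per_g`).
#' @param reference_tgen Reference generation time, hours. Default 7.2 (an
#'   active rhizosphere community).
#' @param min_plausible_tgen,attribution_cutoff Passed to
#'   [classify_interval()].
#' @return A tibble with one row per treatment x interval: `t1`, `t2`,
#'   `n1`, `n2`, `se1`, `se2`, `mu`, `se_mu`, `hourly_fold_change`,
#'   `required_doubling_time`, `replication_attribution`, `interval_class`,
#'   `undefined` flag.
#' @export
growth_table <- function(counts, reference_tgen = 7.2,
                         min_plausible_tgen = 0.5, attribution_cutoff = 0.05) {
  stopifnot(all(c("treatment", "time_h", "active_cells_per_g") %in%
                  names(counts)))
  means <- counts |>
    dplyr::group_by(.data$treatment, .data$time_h) |>
    dplyr::summarise(
      n_mean = mean(.data$active_cells_per_g),
      n_se = if (dplyr::n() >= 2)
        sd(.data$active_cells_per_g) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop") |>
    dplyr::arrange(.data$treatment, .data$time_h)
  rows <- purrr::imap_dfr(split(means, means$treatment), function(df, tr) {
    k <- nrow(df)
    if (k < 2) return(tibble::tibble())
    i <- seq_len(k - 1)
    tibble::tibble(treatment = tr, t1 = df$time_h[i], t2 = df$time_h[i + 1],
                   n1 = df$n_mean[i], n2 = df$n_mean[i + 1],
                   se1 = df$n_se[i], se2 = df$n_se[i + 1])
  })
  purrr::pmap_dfr(rows, function(treatment, t1, t2, n1, n2, se1, se2) {
    dt <- t2 - t1
    ok_ratio <- is.finite(n1) && is.finite(n2) && n1 > 0 && n2 > 0
    grew <- ok_ratio && n2 > n1
    mu <- if (ok_ratio) specific_growth_rate(n1, n2, dt) else NA_real_
    td <- if (grew) required_doubling_time(n1, n2, dt) else NA_real_
    fold <- if (grew) 2^(1 / td) - 1 else NA_real_
    attr_frac <- if (grew)
      replication_attribution(n1, n2, dt, reference_tgen) else NA_real_
    se_mu <- if (ok_ratio && is.finite(se1) && is.finite(se2))
      propagate_se_mu(n1, se1, n2, se2, dt) else NA_real_
    tibble::tibble(
      treatment = treatment, t1 = t1, t2 = t2, n1 = n1, n2 = n2,
      se1 = se1, se2 = se2, mu = mu, se_mu = se_mu,
      hourly_fold_change = fold, required_doubling_time = td,
      replication_attribution = attr_frac,
      interval_class = classify_interval(td, attr_frac, reference_tgen,
                                         min_plausible_tgen,
                                         attribution_cutoff),
      undefined = !grew)
  })
}
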