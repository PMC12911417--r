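#' Plot active cells over time by treatment
#'
#' Bar chart of mean active cells per gram at each time point, by substrate
#' treatment, with standard-error bars. Requires ggplot2.
#'
#' @param counts Counts table from [enumerate_samples()] or
#'   [run_pipeline()]`$counts`.
#' @return A ggplot object.
#' @export
plot_active_cells <- function(counts) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting", class = "soilBONCAT_missing_pkg")
  }
  means <- counts |>
    dplyr::group_by(.data$treatment, .data$time_h) |>
    dplyr::summarise(mean_active = mean(.data$active_cells_per_g),
                     se = sd(.data$active_cells_per_g) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = factor(.data$time_h),
                                      y = .data$mean_active,
                                      fill = .data$treatment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_active - .data$se,
                                        ymax = .data$mean_active + .data$se),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.25) +
    ggplot2::labs(x = "Incubation time (h)",
                  y = "Active cells (g dry soil)⁻¹",
                  fill = "Treatment")
}

#' Plot respiration against active cells with regression bands
#'
#' Scatter of respiration rate versus active cells per gram (log-scale x),
#' with the per-treatment OLS lines and 95% mean-response bands. Requires
#' ggplot2.
#'
#' @param merged Merged table from [run_pipeline()]`$merged`.
#' @param log_base Log base used for the fits. Default 10.
#' @return A ggplot object.
#' @export
plot_respiration_regression <- function(merged, log_base = 10) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting", class = "soilBONCAT_missing_pkg")
  }
  ok <- merged[is.finite(merged$active_cells_per_g) &
                 merged$active_cells_per_g > 0, ]
  bands <- purrr::imap_dfr(split(ok, ok$treatment), function(df, g) {
    if (nrow(df) < 3L) return(tibble::tibble())
    fit <- suppressWarnings(
      fit_loglinear(df$respiration_rate, df$active_cells_per_g, g, log_base))
    dplyr::mutate(confidence_band(fit), treatment = g)
  })
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$active_cells_per_g,
                                   y = .data$respiration_rate,
                                   colour = .data$treatment)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_ribbon(data = bands,
                         ggplot2::aes(y = .data$fit, ymin = .data$lwr,
                                      ymax = .data$upr,
                                      fill = .data$treatment),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(data = bands, ggplot2::aes(y = .data$fit)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Active cells (g dry soil)⁻¹",
                  y = "Respiration (µmol CO₂ g⁻¹ h⁻¹)",
                  colour = "Treatment", fill = "Treatment")
}
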