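#' Volume of suspension analyzed during an acquisition
#'
#' @param flow_rate Sample flow rate, uL per minute.
#' @param duration Acquisition time, seconds.
#' @return Analyzed volume in uL (`flow_rate * duration / 60`).
#' @examples
#' analyzed_volume(22.6, 120) # 45.2
#' @export
analyzed_volume <- function(flow_rate, duration) {
  assert_positive(flow_rate, "flow_rate")
  assert_positive(duration, "duration")
  flow_rate * duration / 60
}

#' Compose a dilution factor from named steps
#'
#' Sample preparation dilutes the soil extract in several steps (e.g. adding
#' glycerol to an aliquot, washes, a final dilution before acquisition). The
#' net suspension-to-tube factor is their product; naming the steps keeps the
#' chain auditable.
#'
#' @param ... Named (or unnamed) positive per-step dilution factors; a value
#'   below 1 denotes a concentration step.
#' @return The product, a single dilution factor.
#' @examples
#' compose_dilution(glycerol = 1.5, final = 4) # 6
#' @export
compose_dilution <- function(...) {
  steps <- c(...)
  if (length(steps) == 0L) return(1)
  if (any(!is.finite(steps) | steps <= 0)) {
    abort("all dilution steps must be positive and finite",
          class = "soilBONCAT_invalid_parameter")
  }
  prod(steps)
}

#' Convert corrected event counts to cells per gram dry soil
#'
#' Scales a background-corrected event count by the analyzed volume, the
#' dilution chain, the extraction volume and the dry soil mass:
#' `cells_per_g = events / analyzed_volume_uL * dilution_factor *
#' extract_volume_mL * 1000 / dry_soil_mass_g`. The result counts
#' extractable cells only; no extraction-efficiency correction is applied.
#'
#' @param corrected_events Non-negative corrected event count.
#' @param acq An [acquisition_settings()].
#' @return Cells per gram dry soil.
#' @examples
#' acq <- acquisition_settings(dilution_factor = 10)
#' events_to_cells_per_g(904, acq) # 1e6
#' @export
events_to_cells_per_g <- function(corrected_events, acq) {
  assert_nonneg(corrected_events, "corrected_events")
  stopifnot(inherits(acq, "acquisition_settings"))
  av <- analyzed_volume(acq$flow_rate, acq$duration)
  corrected_events / av * acq$dilution_factor * acq$extract_volume * 1000 /
    acq$dry_soil_mass
}

#' Active cells as a percentage of total cells
#'
#' @param active_cells_per_g,total_cells_per_g Corrected per-gram counts.
#' @return A list: `percent` (100 * active / total; 0 when total is 0) and
#'   `degenerate` (`TRUE` when total is 0).
#' @export
active_fraction <- function(active_cells_per_g, total_cells_per_g) {
  assert_nonneg(active_cells_per_g, "active_cells_per_g")
  assert_nonneg(total_cells_per_g, "total_cells_per_g")
  if (total_cells_per_g == 0) {
    return(list(percent = 0, degenerate = TRUE))
  }
  list(percent = 100 * active_cells_per_g / total_cells_per_g,
       degenerate = FALSE)
}

#' Build the tidy per-sample counts table
#'
#' Applies [subtract_background()] arithmetic already done upstream to the
#' enumeration formula for each sample: corrected total and active events are
#' scaled to cells per gram dry soil and the active percentage is attached,
#' along with the zeroing/clamping flags.
#'
#' @param corrected Named list of `corrected_counts`, one per sample id.
#' @param metadata Tibble with one row per sample id (columns `sample_id`,
#'   `treatment`, `time_h`, ...).
#' @param acq_by_sample Either a single [acquisition_settings()] used for all
#'   samples or a named list keyed by sample id.
#' @return A tibble: sample_id, treatment, time_h, replicate, batch_id,
#'   analyzed_volume, total_cells_per_g, active_cells_per_g,
#'   active_fraction_pct, zeroed_active, clamped_total, degenerate_fraction.
#' @export
enumerate_samples <- function(corrected, metadata, acq_by_sample) {
  rows <- lapply(names(corrected), function(sid) {
    cc <- corrected[[sid]]
    acq <- if (inherits(acq_by_sample, "acquisition_settings")) acq_by_sample
           else acq_by_sample[[sid]]
    total <- events_to_cells_per_g(cc$total_events_corrected, acq)
    active <- events_to_cells_per_g(cc$active_events_corrected, acq)
    af <- active_fraction(active, total)
    tibble::tibble(sample_id = sid,
                   analyzed_volume = analyzed_volume(acq$flow_rate, acq$duration),
                   total_cells_per_g = total, active_cells_per_g = active,
                   active_fraction_pct = af$percent,
                   zeroed_active = cc$zeroed_active,
                   clamped_total = cc$clamped_total,
                   degenerate_fraction = af$degenerate)
  })
  dplyr::left_join(metadata, dplyr::bind_rows(rows), by = "sample_id")
}
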