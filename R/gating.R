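#' Fit a scatter gate from a reference event table
#'
#' Forward- and side-scatter bounds constrain the size of particles examined.
#' The bounds are nearest-rank empirical quantiles of the reference table's
#' `fsc` and `ssc` values; events outside either interval are excluded from
#' all downstream counts.
#'
#' @param events Reference `event_table` (non-empty).
#' @param low_q,high_q Lower/upper quantiles, `0 <= low_q < high_q <= 1`.
#' @return A list of class `scatter_gate` with `fsc` and `ssc` bound pairs.
#' @export
fit_scatter_gate <- function(events, low_q = 0.001, high_q = 0.999) {
  if (nrow(events) == 0L) {
    abort("cannot fit a scatter gate on an empty event table",
          class = "soilBONCAT_insufficient_data")
  }
  if (!(low_q >= 0 && low_q < high_q && high_q <= 1)) {
    abort("need 0 <= low_q < high_q <= 1", class = "soilBONCAT_invalid_parameter")
  }
  structure(list(
    fsc = c(quantile_nearest_rank(events$fsc, low_q),
            quantile_nearest_rank(events$fsc, high_q)),
    ssc = c(quantile_nearest_rank(events$ssc, low_q),
            quantile_nearest_rank(events$ssc, high_q))),
    class = "scatter_gate")
}

in_scatter_gate <- function(events, scatter) {
  if (is.null(scatter)) return(rep(TRUE, nrow(events)))
  events$fsc >= scatter$fsc[1] & events$fsc <= scatter$fsc[2] &
    events$ssc >= scatter$ssc[1] & events$ssc <= scatter$ssc[2]
}

#' Derive an intensity threshold from a control
#'
#' The SYTO+ (cell vs particle) threshold comes from the APC channel of the
#' killed (autoclaved) control, which contains no cells, so almost everything
#' above it in a real sample is a cell. The BONCAT+ threshold comes from the
#' FITC channel of the SYTO+ population of the HPG-negative control, which
#' contains unlabeled cells only. In both cases the threshold is the
#' nearest-rank empirical quantile of the control distribution — a
#' reproducible stand-in for manual gating; at the default `quantile = 0.999`
#' roughly 0.1% of control events exceed it, consistent with a ~0.2%
#' false-positive discovery rate.
#'
#' @param control Control `event_table` whose `role` matches the channel:
#'   `apc` thresholds require the killed control, `fitc` thresholds the
#'   HPG-negative control.
#' @param channel `"apc"` or `"fitc"`.
#' @param quantile Quantile of the control distribution. Default 0.999.
#' @param restrict_to_syto_pos If `TRUE`, use only control events with
#'   `apc > syto_threshold` (the SYTO+ population).
#' @param syto_threshold Required when `restrict_to_syto_pos = TRUE`.
#' @param scatter Optional `scatter_gate` applied to the control first.
#' @return A single intensity threshold.
#' @export
derive_threshold <- function(control, channel = c("apc", "fitc"),
                             quantile = 0.999, restrict_to_syto_pos = FALSE,
                             syto_threshold = NULL, scatter = NULL) {
  channel <- match.arg(channel)
  assert_proportion(quantile, "quantile")
  expected_role <- switch(channel, apc = "killed_control",
                          fitc = "hpg_negative_control")
  if (!identical(event_role(control), expected_role)) {
    abort(sprintf("%s thresholds must be derived from the %s (got role '%s')",
                  toupper(channel), gsub("_", " ", expected_role),
                  event_role(control)),
          class = "soilBONCAT_invalid_parameter")
  }
  keep <- in_scatter_gate(control, scatter)
  vals <- control[[channel]][keep]
  if (restrict_to_syto_pos) {
    if (is.null(syto_threshold)) {
      abort("`syto_threshold` is required when restricting to SYTO+ events",
            class = "soilBONCAT_invalid_parameter")
    }
    vals <- vals[control$apc[keep] > syto_threshold]
  }
  if (length(vals) == 0L) {
    abort("no control events available to derive a threshold from",
          class = "soilBONCAT_insufficient_data")
  }
  quantile_nearest_rank(vals, quantile)
}

#' Gate set for one batch
#'
#' Bundles the scatter bounds, the two intensity thresholds and the per-batch
#' background event counts used for subtraction. Usually built with
#' [derive_gates()]; construct directly to reproduce manually set gates.
#'
#' @param scatter A `scatter_gate` or `NULL` (no scatter gating).
#' @param syto_threshold APC intensity above which an event is SYTO+ (a cell).
#' @param boncat_threshold FITC intensity above which a SYTO+ event is BONCAT+.
#' @param syto_background_events SYTO+ events in the batch's killed control.
#' @param boncat_background_events BONCAT+ events in the batch's HPG-negative
#'   control.
#' @param batch_id Batch label.
#' @return An object of class `gate_set`.
#' @export
gate_set <- function(scatter = NULL, syto_threshold, boncat_threshold,
                     syto_background_events = 0, boncat_background_events = 0,
                     batch_id = "batch1") {
  stopifnot(!is.na(syto_threshold), !is.na(boncat_threshold))
  assert_nonneg(syto_background_events, "syto_background_events")
  assert_nonneg(boncat_background_events, "boncat_background_events")
  structure(list(scatter = scatter, syto_threshold = syto_threshold,
                 boncat_threshold = boncat_threshold,
                 syto_background_events = syto_background_events,
                 boncat_background_events = boncat_background_events,
                 batch_id = batch_id),
            class = "gate_set")
}

#' Derive the full gate set for a batch from its two controls
#'
#' Fits the scatter gate on the HPG-negative control (the control that
#' contains cells), derives the SYTO+ threshold from the killed control's APC
#' values and the BONCAT+ threshold from the FITC values of the SYTO+
#' population of the HPG-negative control, then records the two background
#' event counts by gating each control with the finished thresholds.
#'
#' @param killed Killed-control `event_table`.
#' @param hpg_negative HPG-negative-control `event_table`.
#' @param scatter_low_q,scatter_high_q Scatter-gate quantiles.
#' @param threshold_q Threshold quantile for both intensity thresholds.
#' @return A `gate_set` for the controls' batch.
#' @export
derive_gates <- function(killed, hpg_negative, scatter_low_q = 0.001,
                         scatter_high_q = 0.999, threshold_q = 0.999) {
  if (!identical(event_batch(killed), event_batch(hpg_negative))) {
    abort("controls must come from the same batch",
          class = "soilBONCAT_invalid_parameter")
  }
  scatter <- fit_scatter_gate(hpg_negative, scatter_low_q, scatter_high_q)
  syto_thr <- derive_threshold(killed, "apc", threshold_q, scatter = scatter)
  boncat_thr <- derive_threshold(hpg_negative, "fitc", threshold_q,
                                 restrict_to_syto_pos = TRUE,
                                 syto_threshold = syto_thr, scatter = scatter)
  gates <- gate_set(scatter, syto_thr, boncat_thr, batch_id = event_batch(killed))
  gates$syto_background_events <- apply_gates(killed, gates)$n_syto_pos
  gates$boncat_background_events <- apply_gates(hpg_negative, gates)$n_boncat_pos
  gates
}

#' Apply a gate set to an event table
#'
#' Gating proceeds in the acquisition order: scatter bounds first, then the
#' SYTO+ threshold on APC (strictly greater), then the BONCAT+ threshold on
#' FITC (strictly greater) within the SYTO+ population. Events exactly at a
#' threshold count as negative.
#'
#' @param events An `event_table`.
#' @param gates A `gate_set`.
#' @return A list of class `gated_counts`: `n_events_total` (events inside
#'   the scatter gate), `n_syto_pos`, `n_boncat_pos`, plus `batch_id`.
#' @export
apply_gates <- function(events, gates) {
  stopifnot(inherits(gates, "gate_set"))
  in_gate <- in_scatter_gate(events, gates$scatter)
  syto <- in_gate & events$apc > gates$syto_threshold
  boncat <- syto & events$fitc > gates$boncat_threshold
  structure(list(n_events_total = sum(in_gate), n_syto_pos = sum(syto),
                 n_boncat_pos = sum(boncat), batch_id = gates$batch_id),
            class = "gated_counts")
}

#' Subtract per-batch control backgrounds from gated counts
#'
#' Removes electronic noise and dye retention on particles using the batch's
#' controls: the killed control's SYTO+ count is subtracted from the sample's
#' SYTO+ count (clamped at zero), and the HPG-negative control's BONCAT+
#' count from the sample's BONCAT+ count. A sample whose BONCAT+ count is
#' less than or equal to the control's is recorded as having zero active
#' cells (`zeroed_active` flag). A final clamp enforces
#' `active <= total`.
#'
#' @param sample `gated_counts` for the sample.
#' @param gates The batch's `gate_set` (carries the background counts).
#' @return A list of class `corrected_counts`: `total_events_corrected`,
#'   `active_events_corrected`, `zeroed_active`, `clamped_total`.
#' @export
subtract_background <- function(sample, gates) {
  stopifnot(inherits(sample, "gated_counts"), inherits(gates, "gate_set"))
  if (!is.null(sample$batch_id) && !is.null(gates$batch_id) &&
      !identical(sample$batch_id, gates$batch_id)) {
    abort("sample and gate set come from different batches",
          class = "soilBONCAT_invalid_parameter")
  }
  clamped_total <- sample$n_syto_pos < gates$syto_background_events
  total <- max(0, sample$n_syto_pos - gates$syto_background_events)
  zeroed <- sample$n_boncat_pos <= gates$boncat_background_events
  active <- if (zeroed) 0 else sample$n_boncat_pos - gates$boncat_background_events
  active <- min(active, total)
  structure(list(total_events_corrected = total,
                 active_events_corrected = active,
                 zeroed_active = zeroed, clamped_total = clamped_total),
            class = "corrected_counts")
}
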