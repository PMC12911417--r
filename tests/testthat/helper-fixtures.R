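# Shared fixtures: a well-separated population and a small acquisition, so
# thresholds derived from controls cleanly split cells/particles and
# active/inactive.

sep_truth <- function(cells_per_g = 5e6, active_fraction = 0.3,
                      particle_rate = 50) {
  population_truth(cells_per_g = cells_per_g,
                   active_fraction = active_fraction,
                   cell_apc_logmean = log(5e3), cell_apc_logsd = 0.3,
                   active_fitc_logmean = log(5e3), active_fitc_logsd = 0.3,
                   inactive_fitc_logmean = log(30), inactive_fitc_logsd = 0.4,
                   particle_rate = particle_rate,
                   particle_apc_logmean = log(20), particle_apc_logsd = 0.5,
                   particle_fitc_logmean = log(20), particle_fitc_logsd = 0.5)
}

small_acq <- function(dilution_factor = 4) {
  acquisition_settings(dilution_factor = dilution_factor)
}

# hand-buildable event table: channels given directly
manual_events <- function(fsc, ssc, fitc, apc, role = "sample",
                          batch_id = "b1") {
  event_table(fsc, ssc, fitc, apc, acq = acquisition_settings(),
              role = role, batch_id = batch_id)
}

# independent per-event linear-scan oracle for the three-stage gate
scan_oracle <- function(events, gates) {
  n_total <- 0L; n_syto <- 0L; n_boncat <- 0L
  for (i in seq_len(nrow(events))) {
    in_gate <- TRUE
    if (!is.null(gates$scatter)) {
      in_gate <- events$fsc[i] >= gates$scatter$fsc[1] &&
        events$fsc[i] <= gates$scatter$fsc[2] &&
        events$ssc[i] >= gates$scatter$ssc[1] &&
        events$ssc[i] <= gates$scatter$ssc[2]
    }
    if (!in_gate) next
    n_total <- n_total + 1L
    if (events$apc[i] > gates$syto_threshold) {
      n_syto <- n_syto + 1L
      if (events$fitc[i] > gates$boncat_threshold) n_boncat <- n_boncat + 1L
    }
  }
  list(n_events_total = n_total, n_syto_pos = n_syto, n_boncat_pos = n_boncat)
}
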