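#' Acquisition settings for a flow-cytometry run
#'
#' Bundles the instrument and sample-preparation quantities needed to convert
#' gated event counts into cells per gram dry soil: the measured flow rate of
#' the instrument's low-flow setting, the acquisition duration, the net
#' dilution applied between the soil extract and the tube that was run, the
#' extraction volume and the oven-dry soil mass.
#'
#' @param flow_rate Sample flow rate, uL per minute. Default 22.6, the
#'   measured low-flow-rate setting used for soil extracts.
#' @param duration Acquisition time, seconds. Default 120.
#' @param dilution_factor Net suspension-to-tube dilution (>= 1 means the
#'   extract was diluted before acquisition). See [compose_dilution()] to
#'   build it from named steps.
#' @param extract_volume Extraction buffer volume, mL. Default 5 (5 mL
#'   Tween/PBS per tube).
#' @param dry_soil_mass Oven-dry soil mass, g. Default 1.
#' @return An object of class `acquisition_settings`.
#' @examples
#' acq <- acquisition_settings()
#' analyzed_volume(acq$flow_rate, acq$duration) # 45.2 uL
#' @export
acquisition_settings <- function(flow_rate = 22.6, duration = 120,
                                 dilution_factor = 1, extract_volume = 5,
                                 dry_soil_mass = 1) {
  assert_positive(flow_rate, "flow_rate")
  assert_positive(duration, "duration")
  assert_positive(dilution_factor, "dilution_factor")
  assert_positive(extract_volume, "extract_volume")
  assert_positive(dry_soil_mass, "dry_soil_mass")
  structure(list(flow_rate = flow_rate, duration = duration,
                 dilution_factor = dilution_factor,
                 extract_volume = extract_volume,
                 dry_soil_mass = dry_soil_mass),
            class = "acquisition_settings")
}

#' Ground-truth population parameters for the simulator
#'
#' Describes the three event sources the simulator mixes, emulating what a
#' soil extract looks like on the cytometer: cells (SYTO59 counterstain high
#' in the red "APC" channel), of which a fraction is translationally active
#' (BONCAT click dye high in the green "FITC" channel), and soil
#' particles/electronic noise (low APC). Fluorescence and scatter intensities
#' are log-normal per channel, the standard positive-valued model for
#' cytometry intensities; scatter is uncorrelated with fluorescence and only
#' exercises the scatter gate.
#'
#' @param cells_per_g True extractable cells per gram dry soil.
#' @param active_fraction True proportion of cells that are translationally
#'   active, in \[0, 1\].
#' @param cell_apc_logmean,cell_apc_logsd Log-scale location/sd of the cell
#'   APC (counterstain) signal.
#' @param active_fitc_logmean,active_fitc_logsd Log-scale location/sd of the
#'   FITC (BONCAT) signal of active cells.
#' @param inactive_fitc_logmean,inactive_fitc_logsd Same for inactive cells
#'   (unlabeled background fluorescence). Must sit below the active location:
#'   the populations are assumed separable.
#' @param particle_rate Background particle events per uL analyzed.
#' @param particle_apc_logmean,particle_apc_logsd,particle_fitc_logmean,particle_fitc_logsd
#'   Particle signal parameters (low APC by assumption).
#' @param cell_scatter_logmean,cell_scatter_logsd,particle_scatter_logmean,particle_scatter_logsd
#'   Log-scale forward/side-scatter parameters.
#' @return An object of class `population_truth`.
#' @export
population_truth <- function(cells_per_g = 5e6, active_fraction = 0.05,
                             cell_apc_logmean = log(5e3), cell_apc_logsd = 0.4,
                             active_fitc_logmean = log(3e3),
                             active_fitc_logsd = 0.5,
                             inactive_fitc_logmean = log(50),
                             inactive_fitc_logsd = 0.6,
                             particle_rate = 50,
                             particle_apc_logmean = log(30),
                             particle_apc_logsd = 0.8,
                             particle_fitc_logmean = log(30),
                             particle_fitc_logsd = 0.8,
                             cell_scatter_logmean = log(2e4),
                             cell_scatter_logsd = 0.4,
                             particle_scatter_logmean = log(8e3),
                             particle_scatter_logsd = 0.9) {
  assert_nonneg(cells_per_g, "cells_per_g")
  assert_proportion(active_fraction, "active_fraction")
  assert_nonneg(particle_rate, "particle_rate")
  if (active_fitc_logmean <= inactive_fitc_logmean) {
    abort("active FITC log-mean must exceed the inactive log-mean (separability)",
          class = "soilBONCAT_invalid_parameter")
  }
  structure(
    list(cells_per_g = cells_per_g, active_fraction = active_fraction,
         cell_apc_logmean = cell_apc_logmean, cell_apc_logsd = cell_apc_logsd,
         active_fitc_logmean = active_fitc_logmean,
         active_fitc_logsd = active_fitc_logsd,
         inactive_fitc_logmean = inactive_fitc_logmean,
         inactive_fitc_logsd = inactive_fitc_logsd,
         particle_rate = particle_rate,
         particle_apc_logmean = particle_apc_logmean,
         particle_apc_logsd = particle_apc_logsd,
         particle_fitc_logmean = particle_fitc_logmean,
         particle_fitc_logsd = particle_fitc_logsd,
         cell_scatter_logmean = cell_scatter_logmean,
         cell_scatter_logsd = cell_scatter_logsd,
         particle_scatter_logmean = particle_scatter_logmean,
         particle_scatter_logsd = particle_scatter_logsd),
    class = "population_truth")
}

#' Construct an event table
#'
#' An event table is a tibble with one row per recorded event and the four
#' optical channels as columns (`fsc`, `ssc`, `fitc`, `apc`), carrying the
#' acquisition settings, the sample role (`sample`, `killed_control` or
#' `hpg_negative_control`) and a batch label as attributes. Simulated tables
#' additionally carry a `truth_label` column partitioning events into
#' `active`, `inactive` and `particle`.
#'
#' @param fsc,ssc,fitc,apc Numeric channel vectors of equal length; all
#'   values must be finite.
#' @param acq An [acquisition_settings()] object.
#' @param role One of `"sample"`, `"killed_control"`, `"hpg_negative_control"`.
#' @param batch_id Batch label; controls are shared within a batch.
#' @param truth_label Optional per-event ground-truth labels.
#' @return A tibble of class `event_table`.
#' @export
event_table <- function(fsc, ssc, fitc, apc, acq, role = "sample",
                        batch_id = "batch1", truth_label = NULL) {
  role <- match.arg(role, c("sample", "killed_control", "hpg_negative_control"))
  stopifnot(inherits(acq, "acquisition_settings"))
  n <- length(fsc)
  if (length(ssc) != n || length(fitc) != n || length(apc) != n) {
    abort("channel vectors must have equal length", class = "soilBONCAT_malformed")
  }
  vals <- c(fsc, ssc, fitc, apc)
  if (length(vals) && !all(is.finite(vals))) {
    abort("all channel intensities must be finite", class = "soilBONCAT_malformed")
  }
  tbl <- tibble::tibble(fsc = as.double(fsc), ssc = as.double(ssc),
                        fitc = as.double(fitc), apc = as.double(apc))
  if (!is.null(truth_label)) {
    stopifnot(length(truth_label) == n)
    tbl$truth_label <- as.character(truth_label)
  }
  structure(tbl, acq = acq, role = role, batch_id = batch_id,
            class = c("event_table", class(tbl)))
}

event_role <- function(events) attr(events, "role", exact = TRUE)
event_acq <- function(events) attr(events, "acq", exact = TRUE)
event_batch <- function(events) attr(events, "batch_id", exact = TRUE)

# expected cell events in the analyzed volume given the enumeration chain
expected_cell_events <- function(truth, acq) {
  av <- analyzed_volume(acq$flow_rate, acq$duration)
  truth$cells_per_g * acq$dry_soil_mass / (acq$extract_volume * 1000) /
    acq$dilution_factor * av
}

draw_events <- function(n_active, n_inactive, n_particle, truth) {
  n <- n_active + n_inactive + n_particle
  lab <- rep(c("active", "inactive", "particle"),
             c(n_active, n_inactive, n_particle))
  fsc <- ssc <- fitc <- apc <- numeric(n)
  is_cell <- lab != "particle"
  nc <- sum(is_cell); np <- n - nc
  fsc[is_cell] <- rlnorm(nc, truth$cell_scatter_logmean, truth$cell_scatter_logsd)
  ssc[is_cell] <- rlnorm(nc, truth$cell_scatter_logmean, truth$cell_scatter_logsd)
  apc[is_cell] <- rlnorm(nc, truth$cell_apc_logmean, truth$cell_apc_logsd)
  fitc[lab == "active"] <- rlnorm(n_active, truth$active_fitc_logmean,
                                  truth$active_fitc_logsd)
  fitc[lab == "inactive"] <- rlnorm(n_inactive, truth$inactive_fitc_logmean,
                                    truth$inactive_fitc_logsd)
  fsc[!is_cell] <- rlnorm(np, truth$particle_scatter_logmean,
                          truth$particle_scatter_logsd)
  ssc[!is_cell] <- rlnorm(np, truth$particle_scatter_logmean,
                          truth$particle_scatter_logsd)
  apc[!is_cell] <- rlnorm(np, truth$particle_apc_logmean, truth$particle_apc_logsd)
  fitc[!is_cell] <- rlnorm(np, truth$particle_fitc_logmean,
                           truth$particle_fitc_logsd)
  # shuffle so event order carries no information
  ord <- sample.int(n)
  list(fsc = fsc[ord], ssc = ssc[ord], fitc = fitc[ord], apc = apc[ord],
       label = lab[ord])
}

#' Simulate a flow-cytometry event table
#'
#' Draws cell and particle events for the volume analyzed during one
#' acquisition. Event counts are Poisson with mean equal to the enumeration
#' contract (cells per gram, scaled through soil mass, extract volume,
#' dilution and analyzed volume); each cell is active with probability
#' `active_fraction`; intensities follow the log-normal channel models in the
#' [population_truth()]. Ground-truth labels are kept in a `truth_label`
#' column.
#'
#' @param truth A [population_truth()].
#' @param acq An [acquisition_settings()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @param role,batch_id Passed to [event_table()].
#' @return An `event_table` with a `truth_label` column.
#' @examples
#' tab <- simulate_event_table(population_truth(), acquisition_settings(), seed = 1)
#' table(tab$truth_label)
#' @export
simulate_event_table <- function(truth, acq, seed, role = "sample",
                                 batch_id = "batch1") {
  stopifnot(inherits(truth, "population_truth"),
            inherits(acq, "acquisition_settings"))
  av <- analyzed_volume(acq$flow_rate, acq$duration)
  withr::with_seed(seed, {
    n_cells <- rpois(1L, expected_cell_events(truth, acq))
    n_active <- if (n_cells > 0) sum(runif(n_cells) < truth$active_fraction) else 0L
    n_particle <- rpois(1L, truth$particle_rate * av)
    ev <- draw_events(n_active, n_cells - n_active, n_particle, truth)
  })
  event_table(ev$fsc, ev$ssc, ev$fitc, ev$apc, acq = acq, role = role,
              batch_id = batch_id, truth_label = ev$label)
}

#' Simulate the two gating controls
#'
#' The killed control emulates an autoclaved soil extract: particle events
#' only, no cells, used to place the SYTO+ (cell vs particle) threshold and
#' the total-count background. The HPG-negative control emulates a replicate
#' incubated with water instead of HPG: cells are present but none carries
#' the BONCAT label, so every cell draws its FITC intensity from the inactive
#' distribution; it places the BONCAT+ threshold and the active-count
#' background.
#'
#' @inheritParams simulate_event_table
#' @return A list with elements `killed` and `hpg_negative`, both
#'   `event_table`s.
#' @export
simulate_controls <- function(truth, acq, seed, batch_id = "batch1") {
  stopifnot(inherits(truth, "population_truth"),
            inherits(acq, "acquisition_settings"))
  av <- analyzed_volume(acq$flow_rate, acq$duration)
  withr::with_seed(derive_seed(seed, "killed"), {
    n_particle <- rpois(1L, truth$particle_rate * av)
    ev_k <- draw_events(0L, 0L, n_particle, truth)
  })
  withr::with_seed(derive_seed(seed, "hpg_negative"), {
    n_cells <- rpois(1L, expected_cell_events(truth, acq))
    n_particle <- rpois(1L, truth$particle_rate * av)
    ev_h <- draw_events(0L, n_cells, n_particle, truth)
  })
  list(
    killed = event_table(ev_k$fsc, ev_k$ssc, ev_k$fitc, ev_k$apc, acq = acq,
                         role = "killed_control", batch_id = batch_id,
                         truth_label = ev_k$label),
    hpg_negative = event_table(ev_h$fsc, ev_h$ssc, ev_h$fitc, ev_h$apc,
                               acq = acq, role = "hpg_negative_control",
                               batch_id = batch_id, truth_label = ev_h$label))
}

#' Ground-truth CO2 detector response
#'
#' Linear detector model `micromol = slope * reading + intercept` used by the
#' simulator; [fit_co2_calibration()] recovers it from the standards table.
#'
#' @param slope Micromoles CO2 per detector unit.
#' @param intercept Micromoles CO2 at zero reading.
#' @return An object of class `calibration_truth`.
#' @export
calibration_truth <- function(slope = 0.002, intercept = 0) {
  assert_positive(slope, "slope")
  structure(list(slope = slope, intercept = intercept),
            class = "calibration_truth")
}

#' Simulate a headspace CO2 measurement
#'
#' Computes the true accumulated headspace CO2 for a tube respiring at
#' `true_rate` for `accumulation_h` hours on top of the ambient background,
#' inverts the detector model to a reading, adds detector noise, and emits a
#' standards table spanning the reading plus an ambient reading — everything
#' the respiration module needs for a full round trip.
#'
#' @param true_rate True respiration rate, umol CO2 per g dry soil per hour.
#' @param acq An [acquisition_settings()] (supplies the dry soil mass).
#' @param accumulation_h Sealed accumulation time before sampling, hours.
#' @param curve_truth A [calibration_truth()].
#' @param ambient_micromol Ambient CO2 in the sealed headspace, umol.
#' @param noise_sd Additive detector noise sd, detector units.
#' @param seed Integer seed.
#' @return A list: `reading` (detector units), `standards` (tibble of
#'   `known_micromol`, `reading`), `ambient_reading`, `true_micromol`.
#' @export
simulate_headspace <- function(true_rate, acq, accumulation_h,
                               curve_truth = calibration_truth(),
                               ambient_micromol = 0.17, noise_sd = 0,
                               seed = 1L) {
  assert_nonneg(true_rate, "true_rate")
  assert_positive(accumulation_h, "accumulation_h")
  assert_nonneg(ambient_micromol, "ambient_micromol")
  assert_nonneg(noise_sd, "noise_sd")
  stopifnot(inherits(curve_truth, "calibration_truth"),
            inherits(acq, "acquisition_settings"))
  true_umol <- true_rate * acq$dry_soil_mass * accumulation_h + ambient_micromol
  to_reading <- function(umol) (umol - curve_truth$intercept) / curve_truth$slope
  noise <- if (noise_sd > 0) withr::with_seed(seed, rnorm(1, 0, noise_sd)) else 0
  std_umol <- seq(0, max(2, 2 * true_umol), length.out = 6L)
  list(reading = to_reading(true_umol) + noise,
       standards = tibble::tibble(known_micromol = std_umol,
                                  reading = to_reading(std_umol)),
       ambient_reading = to_reading(ambient_micromol),
       true_micromol = true_umol)
}

demo_truth_row <- function(total, active, base = population_truth()) {
  tr <- base
  tr$cells_per_g <- total
  tr$active_fraction <- active / total
  tr
}

#' Demo experiment design
#'
#' Three substrate treatments (glucose, galactose, water) crossed with four
#' incubation lengths (2, 6, 12, 24 h) and six replicate tubes per cell —
#' the layout of a short-term substrate-induced-respiration incubation. The
#' built-in ground truth follows the qualitative pattern such experiments
#' show: extractable totals near 5e6 cells per g at 2 h, active fractions
#' rising from ~0.1% to 27%, glucose responding fastest (its 2-to-6-h
#' active-cell fold change of 87.55 corresponds to a 0.62-h required doubling
#' time), galactose slow and steady, water lowest; respiration ordered
#' glucose > galactose > water and rising by 24 h.
#'
#' @param seed Master seed; per-replicate seeds are derived by stable hashing
#'   of (seed, treatment, time, replicate).
#' @param replicates Replicate tubes per treatment x time cell. Default 6.
#' @param dilution_factor Net extract-to-tube dilution applied to every
#'   sample. Default 2.
#' @param accumulation_h Headspace accumulation time, hours. Default 2.
#' @param noise_sd Detector noise for headspace readings. Default 2
#'   detector units.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(seed = 1L, replicates = 6L, dilution_factor = 2,
                              accumulation_h = 2, noise_sd = 2) {
  stopifnot(replicates >= 1)
  treatments <- c("glucose", "galactose", "water")
  time_points <- c(2, 6, 12, 24)
  totals <- list(glucose   = c(5e6, 7e6, 1.2e7, 2e7),
                 galactose = c(5e6, 6e6, 7e6, 1e7),
                 water     = c(5e6, 5.5e6, 6.5e6, 8e6))
  actives <- list(glucose   = c(1e4, 8.755e5, 3e6, 5.4e6),
                  galactose = c(2.5e4, 3.5e4, 6e4, 1.8e5),
                  water     = c(5e3, 1.2e4, 5e4, 1.5e5))
  resp <- list(glucose   = c(0.40, 0.55, 0.80, 2.0),
               galactose = c(0.25, 0.35, 0.50, 1.1),
               water     = c(0.10, 0.18, 0.22, 0.35))
  truth <- list(); resp_truth <- list()
  for (tr in treatments) {
    for (i in seq_along(time_points)) {
      key <- paste(tr, time_points[i], sep = "_")
      truth[[key]] <- demo_truth_row(totals[[tr]][i], actives[[tr]][i])
      resp_truth[[key]] <- resp[[tr]][i]
    }
  }
  structure(list(treatments = treatments, time_points = time_points,
                 replicates = as.integer(replicates),
                 truth_by_condition = truth,
                 respiration_truth_by_condition = resp_truth,
                 acq = acquisition_settings(dilution_factor = dilution_factor),
                 accumulation_h = accumulation_h,
                 curve_truth = calibration_truth(),
                 ambient_micromol = 0.17, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Simulate a full incubation experiment
#'
#' Generates, deterministically for a given master seed, one event table and
#' one headspace record per replicate tube plus one killed and one
#' HPG-negative control per batch. Batches correspond to incubation lengths
#' (all tubes harvested together share controls), and the batch controls take
#' their cell population from the water condition at that time point — the
#' HPG-negative control is the water-amended sixth replicate of the batch.
#'
#' @param design An [experiment_design()].
#' @return A list with elements `samples` (list of `event_table`s named by
#'   sample id), `metadata` (tibble), `controls` (per-batch list of
#'   `killed`/`hpg_negative`), `headspace` (tibble of readings),
#'   `standards` (calibration standards tibble), `ambient_reading`,
#'   `truth` (tibble of per-condition ground truth), and `design`.
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  acq <- design$acq
  samples <- list(); meta <- list(); head_rows <- list(); truth_rows <- list()
  max_umol <- 0
  for (tr in design$treatments) {
    for (tp in design$time_points) {
      key <- paste(tr, tp, sep = "_")
      truth <- design$truth_by_condition[[key]]
      if (is.null(truth)) {
        abort(sprintf("no ground truth configured for condition '%s'", key),
              class = "soilBONCAT_config_error")
      }
      rate <- design$respiration_truth_by_condition[[key]]
      if (is.null(rate)) {
        abort(sprintf("no respiration truth configured for condition '%s'", key),
              class = "soilBONCAT_config_error")
      }
      batch <- paste0("t", tp)
      for (r in seq_len(design$replicates)) {
        sid <- sprintf("%s_%gh_r%d", tr, tp, r)
        samples[[sid]] <- simulate_event_table(
          truth, acq, seed = derive_seed(design$seed, tr, tp, r),
          role = "sample", batch_id = batch)
        hs <- simulate_headspace(
          rate, acq, design$accumulation_h, design$curve_truth,
          design$ambient_micromol, design$noise_sd,
          seed = derive_seed(design$seed, "headspace", tr, tp, r))
        max_umol <- max(max_umol, hs$true_micromol)
        meta[[sid]] <- tibble::tibble(
          sample_id = sid, treatment = tr, time_h = tp, replicate = r,
          batch_id = batch, dry_soil_mass = acq$dry_soil_mass,
          dilution_factor = acq$dilution_factor,
          extract_volume = acq$extract_volume)
        head_rows[[sid]] <- tibble::tibble(
          sample_id = sid, reading = hs$reading,
          accumulation_h = design$accumulation_h,
          dry_soil_mass = acq$dry_soil_mass)
      }
      truth_rows[[key]] <- tibble::tibble(
        treatment = tr, time_h = tp,
        total_cells_per_g_true = truth$cells_per_g,
        active_cells_per_g_true = truth$cells_per_g * truth$active_fraction,
        active_fraction_true = truth$active_fraction,
        respiration_rate_true = rate)
    }
  }
  controls <- list()
  for (tp in design$time_points) {
    batch <- paste0("t", tp)
    ctl_truth <- design$truth_by_condition[[paste("water", tp, sep = "_")]]
    if (is.null(ctl_truth)) ctl_truth <- design$truth_by_condition[[1L]]
    controls[[batch]] <- simulate_controls(
      ctl_truth, acq, seed = derive_seed(design$seed, "controls", tp),
      batch_id = batch)
  }
  # one calibration session for the experiment, spanning all readings
  std_umol <- seq(0, max(2, 1.2 * max_umol), length.out = 8L)
  to_reading <- function(umol) (umol - design$curve_truth$intercept) /
    design$curve_truth$slope
  list(samples = samples,
       metadata = dplyr::bind_rows(meta),
       controls = controls,
       headspace = dplyr::bind_rows(head_rows),
       standards = tibble::tibble(known_micromol = std_umol,
                                  reading = to_reading(std_umol)),
       ambient_reading = to_reading(design$ambient_micromol),
       truth = dplyr::bind_rows(truth_rows),
       design = design)
}
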