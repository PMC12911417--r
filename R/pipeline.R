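#' Pipeline run configuration
#'
#' One object holding everything a pipeline run needs. In `synthetic` mode
#' the input is an [experiment_design()] and every stage runs on generated
#' data; in `files` mode the input is a set of CSV paths (per-sample event
#' tables plus per-batch `<batch>_killed.csv` / `<batch>_hpg_negative.csv`
#' controls written by [write_event_table()], a metadata table, headspace
#' readings and calibration standards).
#'
#' @param design An [experiment_design()] (synthetic mode).
#' @param paths Named list for files mode: `events_dir`, `metadata`,
#'   `headspace`, `standards`, `ambient_reading` (a number, detector units).
#' @param scatter_low_q,scatter_high_q Scatter-gate quantiles.
#' @param threshold_q Control quantile for both intensity thresholds.
#' @param reference_tgen Reference generation time for attribution, hours.
#' @param min_plausible_tgen,attribution_cutoff Interval classification
#'   cutoffs (see [classify_interval()]).
#' @param log_base Log base for the respiration regressions.
#' @param out_dir Output directory for stage CSVs and the run log, or `NULL`
#'   to keep results in memory only.
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = experiment_design(), paths = NULL,
                       scatter_low_q = 0.001, scatter_high_q = 0.999,
                       threshold_q = 0.999, reference_tgen = 7.2,
                       min_plausible_tgen = 0.5, attribution_cutoff = 0.05,
                       log_base = 10, out_dir = NULL) {
  mode <- if (is.null(paths)) "synthetic" else "files"
  if (mode == "files") {
    need <- c("events_dir", "metadata", "headspace", "standards",
              "ambient_reading")
    missing_keys <- setdiff(need, names(paths))
    if (length(missing_keys)) {
      abort(sprintf("files mode needs paths: %s",
                    paste(missing_keys, collapse = ", ")),
            class = "soilBONCAT_config_error")
    }
    for (p in paths[c("events_dir", "metadata", "headspace", "standards")]) {
      if (!file.exists(p)) {
        abort(sprintf("path does not exist: %s", p),
              class = "soilBONCAT_config_error")
      }
    }
  }
  assert_proportion(threshold_q, "threshold_q")
  structure(list(mode = mode, design = design, paths = paths,
                 scatter_low_q = scatter_low_q,
                 scatter_high_q = scatter_high_q, threshold_q = threshold_q,
                 reference_tgen = reference_tgen,
                 min_plausible_tgen = min_plausible_tgen,
                 attribution_cutoff = attribution_cutoff,
                 log_base = log_base, out_dir = out_dir),
            class = "run_config")
}

with_stage <- function(stage, sample_id = NULL, expr) {
  tryCatch(expr, error = function(e) {
    where <- if (is.null(sample_id)) stage
             else sprintf("%s [sample %s]", stage, sample_id)
    abort(sprintf("pipeline stage '%s' failed: %s", where,
                  conditionMessage(e)),
          class = "soilBONCAT_stage_error", parent = e)
  })
}

load_file_inputs <- function(paths) {
  metadata <- readr::read_csv(paths$metadata, show_col_types = FALSE,
                              progress = FALSE)
  samples <- list()
  for (sid in metadata$sample_id) {
    f <- file.path(paths$events_dir, paste0(sid, ".csv"))
    if (!file.exists(f)) {
      abort(sprintf("event table missing for sample '%s'", sid),
            class = "soilBONCAT_config_error")
    }
    samples[[sid]] <- read_event_table(f)
  }
  controls <- list()
  for (batch in unique(metadata$batch_id)) {
    fk <- file.path(paths$events_dir, paste0(batch, "_killed.csv"))
    fh <- file.path(paths$events_dir, paste0(batch, "_hpg_negative.csv"))
    if (!file.exists(fk) || !file.exists(fh)) {
      abort(sprintf("missing control event table(s) for batch '%s'", batch),
            class = "soilBONCAT_config_error")
    }
    controls[[batch]] <- list(killed = read_event_table(fk),
                              hpg_negative = read_event_table(fh))
  }
  list(samples = samples, metadata = metadata, controls = controls,
       headspace = readr::read_csv(paths$headspace, show_col_types = FALSE,
                                   progress = FALSE),
       standards = readr::read_csv(paths$standards, show_col_types = FALSE,
                                   progress = FALSE),
       ambient_reading = paths$ambient_reading)
}

#' Run the full quantification pipeline
#'
#' Orchestrates simulate (or load) -> gate -> enumerate -> respire ->
#' kinetics -> relate from one [run_config()]. Controls are shared within a
#' batch; gates and backgrounds are derived per batch from that batch's
#' killed and HPG-negative controls. In synthetic mode a rerun with the same
#' config reproduces every output file byte for byte.
#'
#' @param config A [run_config()].
#' @return A list: `counts` (per-sample enumeration table), `respiration`
#'   (per-sample rates), `merged` (counts + respiration + per-active-cell
#'   respiration), `growth` (per-treatment interval kinetics), `regressions`
#'   (per-treatment and pooled log-linear fits), `gates` (per batch),
#'   `calibration`, `run_log`. Stage CSVs and `run_log.json` are written
#'   under `out_dir` when configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- if (config$mode == "synthetic") {
    with_stage("simulate", expr = simulate_experiment(config$design))
  } else {
    with_stage("load", expr = load_file_inputs(config$paths))
  }

  gates <- list()
  for (batch in names(inputs$controls)) {
    gates[[batch]] <- with_stage(sprintf("gate [batch %s]", batch), expr =
      derive_gates(inputs$controls[[batch]]$killed,
                   inputs$controls[[batch]]$hpg_negative,
                   config$scatter_low_q, config$scatter_high_q,
                   config$threshold_q))
  }

  corrected <- list()
  for (sid in names(inputs$samples)) {
    ev <- inputs$samples[[sid]]
    batch <- event_batch(ev)
    if (is.null(gates[[batch]])) {
      abort(sprintf("no controls available for batch '%s'", batch),
            class = "soilBONCAT_config_error")
    }
    corrected[[sid]] <- with_stage("gate", sid, expr = {
      g <- apply_gates(ev, gates[[batch]])
      g$batch_id <- batch
      subtract_background(g, gates[[batch]])
    })
  }

  acq_by_sample <- lapply(inputs$samples, event_acq)
  counts <- with_stage("enumerate", expr =
    enumerate_samples(corrected, inputs$metadata, acq_by_sample))

  calibration <- with_stage("respire", expr =
    fit_co2_calibration(inputs$standards))
  ambient_micromol <- calibrate_micromol(calibration, inputs$ambient_reading)
  respiration <- purrr::pmap_dfr(inputs$headspace, function(sample_id, reading,
                                                            accumulation_h,
                                                            dry_soil_mass, ...) {
    rr <- with_stage("respire", sample_id, expr =
      respiration_rate(reading, calibration, ambient_micromol,
                       dry_soil_mass, accumulation_h))
    tibble::tibble(sample_id = sample_id,
                   headspace_micromol = rr$headspace_micromol,
                   corrected_micromol = rr$corrected_micromol,
                   respiration_rate = rr$rate, clamped_respiration = rr$clamped)
  })

  merged <- dplyr::left_join(counts, respiration, by = "sample_id")
  merged$respiration_per_active_cell <- purrr::map2_dbl(
    merged$respiration_rate, merged$active_cells_per_g,
    function(r, a) respiration_per_active_cell(r, a)$value)

  growth <- with_stage("kinetics", expr =
    growth_table(counts, config$reference_tgen, config$min_plausible_tgen,
                 config$attribution_cutoff))

  regressions <- with_stage("relate", expr =
    withCallingHandlers(relate_respiration(merged, config$log_base),
                        warning = function(w) {
                          invokeRestart("muffleWarning")
                        }))

  run_log <- list(package = "soilBONCAT",
                  version = as.character(packageVersion("soilBONCAT")),
                  mode = config$mode,
                  seed = if (config$mode == "synthetic")
                    config$design$seed else NA_integer_,
                  config_hash = rlang::hash(config[setdiff(names(config),
                                                           "out_dir")]),
                  n_samples = length(inputs$samples),
                  n_batches = length(gates))

  result <- list(counts = counts, respiration = respiration, merged = merged,
                 growth = growth, regressions = regressions, gates = gates,
                 calibration = calibration, run_log = run_log)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(counts, file.path(config$out_dir, "counts.csv"))
    readr::write_csv(respiration, file.path(config$out_dir, "respiration.csv"))
    readr::write_csv(merged, file.path(config$out_dir, "merged.csv"))
    readr::write_csv(growth, file.path(config$out_dir, "growth.csv"))
    readr::write_csv(regressions, file.path(config$out_dir, "regressions.csv"))
    jsonlite::write_json(run_log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
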