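#' Write an event table to CSV with a metadata header
#'
#' The canonical interchange format for event data: a `#key: value` header
#' block carrying the acquisition settings, role and batch, followed by a
#' plain CSV of the per-event channels. Round-trips through
#' [read_event_table()].
#'
#' @param events An `event_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  acq <- event_acq(events)
  header <- c(
    sprintf("#role: %s", event_role(events)),
    sprintf("#batch_id: %s", event_batch(events)),
    sprintf("#flow_rate: %.15g", acq$flow_rate),
    sprintf("#duration: %.15g", acq$duration),
    sprintf("#dilution_factor: %.15g", acq$dilution_factor),
    sprintf("#extract_volume: %.15g", acq$extract_volume),
    sprintf("#dry_soil_mass: %.15g", acq$dry_soil_mass))
  writeLines(header, path)
  readr::write_csv(tibble::as_tibble(events), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#'
#' @param path File path.
#' @return An `event_table`.
#' @export
read_event_table <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), ":\\s*")
  meta <- setNames(vapply(kv, `[`, character(1), 2L),
                   vapply(kv, `[`, character(1), 1L))
  need <- c("role", "batch_id", "flow_rate", "duration", "dilution_factor",
            "extract_volume", "dry_soil_mass")
  if (!all(need %in% names(meta))) {
    abort(sprintf("event-table header is missing: %s",
                  paste(setdiff(need, names(meta)), collapse = ", ")),
          class = "soilBONCAT_malformed")
  }
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  acq <- acquisition_settings(
    flow_rate = as.numeric(meta[["flow_rate"]]),
    duration = as.numeric(meta[["duration"]]),
    dilution_factor = as.numeric(meta[["dilution_factor"]]),
    extract_volume = as.numeric(meta[["extract_volume"]]),
    dry_soil_mass = as.numeric(meta[["dry_soil_mass"]]))
  event_table(tbl$fsc, tbl$ssc, tbl$fitc, tbl$apc, acq = acq,
              role = meta[["role"]], batch_id = meta[["batch_id"]],
              truth_label = if ("truth_label" %in% names(tbl)) tbl$truth_label)
}
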