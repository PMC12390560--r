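#' Write / read an EMG recording as CSV with a JSON annotation sidecar
#'
#' The signal goes to a two-column CSV (`time_s,emg_mV`, one row per
#' sample); ground-truth annotations go to a sidecar JSON file
#' `{"onsets_s": [...], "offsets_s": [...]}` next to it (same path with a
#' `.annotations.json` suffix unless given).
#'
#' @param rec An [emg_recording][synthesize_emg()].
#' @param path Output CSV path.
#' @param annotations_path Optional sidecar path.
#' @return `path`, invisibly.
#' @export
write_emg_csv <- function(rec, path, annotations_path = NULL) {
  annotations_path <- annotations_path %||%
    sub("\\.csv$", ".annotations.json", path)
  readr::write_csv(tibble::tibble(time_s = rec$time_s, emg_mV = rec$emg_mV),
                   path)
  ann <- annotations(rec)
  jsonlite::write_json(
    list(onsets_s = ann$onset_s, offsets_s = ann$offset_s,
         fs = sampling_rate(rec), seed = attr(rec, "seed")),
    annotations_path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(path, annotations_path = NULL) {
  annotations_path <- annotations_path %||%
    sub("\\.csv$", ".annotations.json", path)
  df <- readr::read_csv(path, show_col_types = FALSE)
  fs <- 1 / stats::median(diff(df$time_s))
  ann <- tibble::tibble(onset_s = double(), offset_s = double())
  seed <- NA_integer_
  if (file.exists(annotations_path)) {
    j <- jsonlite::read_json(annotations_path, simplifyVector = TRUE)
    ann <- tibble::tibble(onset_s = as.double(j$onsets_s),
                          offset_s = as.double(j$offsets_s))
    if (!is.null(j$fs)) fs <- j$fs
    if (!is.null(j$seed)) seed <- j$seed
  }
  new_emg_recording(df$emg_mV, fs, ann, seed)
}

#' Write a boost-converter trace as CSV
#'
#' Columns `time_s,v_out,i_l,duty,load_ohm`.
#'
#' @param trace A `boost_trace` from [simulate_boost()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(as.data.frame(trace), path)
  invisible(path)
}

#' Write a multi-channel waveform set as CSV
#'
#' Columns `time_s,ch1_mA,...,chN_mA`.
#'
#' @param wf A `waveform_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wf, path) {
  readr::write_csv(as.data.frame(wf), path)
  invisible(path)
}

#' Write detection events as JSON
#'
#' A list of `{"t_s": ..., "env_mV": ...}` records.
#'
#' @param events Tibble from [detect_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(events, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' Read a YAML configuration into tensloop configuration objects
#'
#' Recognised top-level blocks: `frontend:`, `detector:`, `plant:`, `pi:`,
#' `timing:`, `pulse:`, `channels:`, `noise:`, `power:`. Each block's keys
#' are passed to the corresponding constructor; omitted blocks get
#' defaults only if `fill_defaults` is set.
#'
#' @param path YAML file path.
#' @param fill_defaults Construct default objects for missing blocks.
#' @return A named list of configuration objects.
#' @export
read_config <- function(path, fill_defaults = TRUE) {
  raw <- yaml::read_yaml(path)
  ctors <- list(
    frontend = frontend_config, detector = detector_config,
    plant = plant_params, pi = pi_config, timing = timing_model,
    pulse = pulse_spec, channels = channel_setup, noise = noise_spec,
    power = power_model
  )
  out <- list()
  for (nm in names(ctors)) {
    if (!is.null(raw[[nm]])) {
      out[[nm]] <- do.call(ctors[[nm]], raw[[nm]])
    } else if (fill_defaults && nm != "pi") {
      out[[nm]] <- ctors[[nm]]()
    }
  }
  out
}
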