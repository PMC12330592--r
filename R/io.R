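#' Write impedance spectra to CSV
#'
#' Long format with columns `frequency_hz`, `z_mag_ohm`, `z_phase_deg`,
#' `electrode_id`.
#'
#' @param spectra A single [impedance_spectrum()] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  if (inherits(spectra, "impedance_spectrum")) spectra <- list(spectra)
  rows <- lapply(spectra, function(s) {
    data.frame(frequency_hz = s$frequency, z_mag_ohm = s$magnitude,
               z_phase_deg = s$phase, electrode_id = s$electrode_id)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read impedance spectra from CSV
#'
#' Header-driven: column order does not matter.
#'
#' @param path CSV path written by [write_spectra_csv()].
#' @return List of [impedance_spectrum()] objects.
#' @export
read_spectra_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frequency_hz", "z_mag_ohm", "z_phase_deg", "electrode_id")
  if (!all(need %in% names(d)))
    stop("spectra CSV missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  lapply(split(d, d$electrode_id), function(g) {
    g <- g[order(g$frequency_hz), ]
    impedance_spectrum(g$electrode_id[1], g$frequency_hz,
                       g$z_mag_ohm, g$z_phase_deg)
  })
}

#' Write a voltage transient to CSV (+ JSON sidecar)
#'
#' The CSV carries `time_s`, `voltage_v`; the sidecar records the pulse
#' train, the generating circuit (if known) and the format version.
#'
#' @param trace A `voltage_transient`.
#' @param path Output CSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_transient <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time, voltage_v = trace$voltage),
                   path, row.names = FALSE)
  side <- list(format_version = 1L,
               pulse_train = unclass(trace$train),
               circuit_truth = if (!is.null(trace$circuit_truth))
                 unclass(trace$circuit_truth) else NULL,
               first_onset = trace$first_onset)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a voltage transient written by [write_transient()]
#'
#' @param path CSV path (sidecar `<path>.json` read when present).
#' @return A `voltage_transient`.
#' @export
read_transient <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "voltage_v") %in% names(d)))
    stop("transient CSV must have time_s and voltage_v columns")
  side_path <- paste0(path, ".json")
  train <- circuit <- first_onset <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$pulse_train))
      train <- do.call(pulse_train, list(
        amplitude = side$pulse_train$amplitude,
        cathodic_pulse_width = side$pulse_train$cathodic_pulse_width,
        interphase_gap = side$pulse_train$interphase_gap,
        pulses_per_burst = side$pulse_train$pulses_per_burst,
        pulse_frequency = side$pulse_train$pulse_frequency,
        burst_frequency = side$pulse_train$burst_frequency,
        cathodic_first = side$pulse_train$cathodic_first,
        sample_rate = side$pulse_train$sample_rate))
    if (!is.null(side$circuit_truth))
      circuit <- circuit_params(side$circuit_truth$rs, side$circuit_truth$rct,
                                side$circuit_truth$cap,
                                side$circuit_truth$alpha)
    first_onset <- side$first_onset
  }
  structure(list(time = d$time_s, voltage = d$voltage_v, current = NULL,
                 train = train, circuit_truth = circuit,
                 first_onset = first_onset),
            class = "voltage_transient")
}

#' Write an array layout as JSON
#'
#' @param layout A [layout_spec()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "layout_spec"))
  obj <- list(format_version = 1L,
              window_diameter_mm = layout$window_diameter,
              electrodes = layout$electrodes,
              traces = lapply(layout$traces %||% list(), function(tr)
                list(x = tr$x, y = tr$y, width_um = tr$width)),
              tapers = lapply(layout$tapers %||% list(), function(tp)
                list(x = tp[, 1], y = tp[, 2])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an array layout written by [write_layout_json()]
#'
#' @param path JSON path.
#' @return A [layout_spec()].
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$window_diameter_mm)) stop("not a layout JSON (no window)")
  electrodes <- if (!is.null(obj$electrodes) && length(obj$electrodes))
    as.data.frame(obj$electrodes) else NULL
  traces <- NULL
  if (!is.null(obj$traces) && length(obj$traces)) {
    tr_list <- if (is.data.frame(obj$traces))
      split(obj$traces, seq_len(nrow(obj$traces))) else obj$traces
    traces <- lapply(tr_list, function(tr)
      list(x = unlist(tr$x), y = unlist(tr$y), width = tr$width_um[[1]]))
    names(traces) <- NULL
  }
  tapers <- NULL
  if (!is.null(obj$tapers) && length(obj$tapers)) {
    tp_list <- if (is.data.frame(obj$tapers))
      split(obj$tapers, seq_len(nrow(obj$tapers))) else obj$tapers
    tapers <- lapply(tp_list, function(tp) cbind(unlist(tp$x), unlist(tp$y)))
    names(tapers) <- NULL
  }
  layout_spec(obj$window_diameter_mm, electrodes, traces, tapers)
}

#' Write a recording session (CSV samples + JSON sidecar)
#'
#' @param session A [recording_session()].
#' @param path Output CSV path (samples x channels); events and metadata
#'   go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  d <- as.data.frame(session$signals)
  names(d) <- session$channel_ids
  utils::write.csv(d, path, row.names = FALSE)
  side <- list(format_version = 1L, sample_rate = session$sample_rate,
               events = session$events, channel_ids = session$channel_ids,
               impedances = session$impedances,
               layout = session$layout)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a recording session written by [write_session()]
#'
#' @param path CSV path.
#' @return A [recording_session()].
#' @export
read_session <- function(path) {
  d <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  events <- if (!is.null(side$events) && length(side$events))
    as.data.frame(side$events) else data.frame(time = numeric(0),
                                               type = character(0))
  layout <- if (!is.null(side$layout) && length(side$layout))
    as.data.frame(side$layout) else NULL
  recording_session(as.matrix(d), side$sample_rate, events = events,
                    channel_ids = side$channel_ids, layout = layout,
                    impedances = unlist(side$impedances))
}

#' Write a provenance manifest beside result files
#'
#' Records inputs, parameters, seed, package version and an MD5 digest of
#' the parameter block so reruns can be matched to their configuration.
#'
#' @param path Output JSON path.
#' @param inputs Character vector of input paths/identifiers.
#' @param parameters Named list of parameters.
#' @param seed Integer seed used for the run.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs = character(0),
                           parameters = list(), seed = NA_integer_) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(parameters, tmp, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  obj <- list(format_version = 1L,
              package = "durakit",
              version = as.character(utils::packageVersion("durakit")),
              inputs = inputs, parameters = parameters,
              seed = seed, config_md5 = hash,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
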