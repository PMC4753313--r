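# EMG trial container, plain-text trial IO, rectification and pre-stimulus
# background statistics.
#
# Conventions used throughout the package: the stimulus is at t = 0 ms,
# latencies are in ms post-stimulus, analysis windows are half-open
# [start, end), sample indices are 0-based, and voltages are in microvolts.

#' Trial metadata
#'
#' Describes the experimental condition a single EMG trial was recorded
#' under: which participant and hand, the recorded muscle, TMS coil
#' orientation, contraction task and assessment timepoint.
#'
#' @param participant_id Character participant identifier.
#' @param hand `"contralateral"` or `"ipsilateral"` to the stimulated
#'   hemisphere.
#' @param muscle Recorded muscle, default `"FDI"` (first dorsal
#'   interosseous).
#' @param coil_orientation Induced-current direction: `"PA"`, `"LM"`,
#'   `"AP"`, or `"none"` when orientation is not manipulated.
#' @param task `"rest"`, `"light_contraction"` (~10-25% of maximum) or
#'   `"max_contraction"`.
#' @param timepoint Assessment timepoint: `"BL"`, `"T10"`, `"T20"` or
#'   `"T40"` (baseline and minutes post-intervention).
#' @param stimulus_intensity Stimulator output as percent of motor
#'   threshold, or `NA`.
#' @param threshold_type `"rMT"`, `"aMT"` or `NA`; which threshold
#'   `stimulus_intensity` refers to.
#' @return A list of class `trial_metadata`.
#' @export
trial_metadata <- function(participant_id = "P01",
                           hand = c("contralateral", "ipsilateral"),
                           muscle = "FDI",
                           coil_orientation = c("none", "PA", "LM", "AP"),
                           task = c("rest", "light_contraction",
                                    "max_contraction"),
                           timepoint = c("BL", "T10", "T20", "T40"),
                           stimulus_intensity = NA_real_,
                           threshold_type = NA_character_) {
  hand <- match.arg(hand)
  coil_orientation <- match.arg(coil_orientation)
  task <- match.arg(task)
  timepoint <- match.arg(timepoint)
  if (!is.na(threshold_type)) {
    threshold_type <- match.arg(threshold_type, c("rMT", "aMT"))
  }
  structure(list(participant_id = as.character(participant_id),
                 hand = hand, muscle = muscle,
                 coil_orientation = coil_orientation,
                 task = task, timepoint = timepoint,
                 stimulus_intensity = as.numeric(stimulus_intensity),
                 threshold_type = threshold_type),
            class = "trial_metadata")
}

#' Single-trial EMG trace
#'
#' One trial's voltage samples together with the sampling rate, the sample
#' index at which the TMS pulse was delivered, and trial metadata.
#'
#' @param samples Numeric vector of voltages in microvolts; all finite.
#' @param sampling_rate Sampling rate in Hz (nominally 2000).
#' @param stimulus_index 0-based sample index of the TMS pulse.
#' @param metadata A [trial_metadata()] object.
#' @return A list of class `emg_trace`.
#' @export
emg_trace <- function(samples, sampling_rate, stimulus_index,
                      metadata = trial_metadata()) {
  if (!is.numeric(samples) || length(samples) == 0) {
    stop_field("samples", "must be a non-empty numeric vector")
  }
  if (any(!is.finite(samples))) {
    stop_field("samples", "must all be finite")
  }
  check_number(sampling_rate, "sampling_rate", lower = .Machine$double.eps)
  check_number(stimulus_index, "stimulus_index", lower = 0,
               upper = length(samples) - 1)
  if (!inherits(metadata, "trial_metadata")) {
    stop_field("metadata", "must be a trial_metadata object")
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate),
                 stimulus_index = as.integer(stimulus_index),
                 metadata = metadata),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "<emg_trace> %d samples @ %g Hz, stimulus at index %d (t = 0 ms)\n",
    length(x$samples), x$sampling_rate, x$stimulus_index))
  cat(sprintf("  %s | %s hand | %s | orientation %s | %s | %s\n",
              md$participant_id, md$hand, md$muscle, md$coil_orientation,
              md$task, md$timepoint))
  invisible(x)
}

# ms post-stimulus for each 0-based sample index
trace_time_ms <- function(trace) {
  (seq_along(trace$samples) - 1 - trace$stimulus_index) /
    trace$sampling_rate * 1000
}

# 1-based sample index of time t (ms post-stimulus), rounding half up
time_to_index <- function(trace, t_ms) {
  as.integer(floor(t_ms * trace$sampling_rate / 1000 + 0.5)) +
    trace$stimulus_index + 1L
}

index_to_time <- function(trace, idx) {
  (idx - 1L - trace$stimulus_index) / trace$sampling_rate * 1000
}

#' Full-wave rectification
#'
#' @param x An `emg_trace` or a numeric vector.
#' @return Numeric vector of absolute voltages, same length as the input.
#' @export
rectify <- function(x) {
  if (inherits(x, "emg_trace")) x <- x$samples
  abs(x)
}

#' Pre-stimulus background EMG statistics
#'
#' Mean and standard deviation of the rectified signal over a pre-stimulus
#' window, used as the reference level for MEP and silent-period threshold
#' criteria.
#'
#' @param trace An [emg_trace()].
#' @param window_start_ms,window_end_ms Window bounds in ms relative to the
#'   stimulus (both non-positive, half-open `[start, end)`). The default
#'   `[-105, -5)` window is 100 ms long and ends 5 ms before the pulse to
#'   stay clear of pre-trigger artifacts.
#' @return A list of class `background_stats` with `mean_rectified`,
#'   `sd_rectified` (microvolts) and the window bounds.
#' @export
background_stats <- function(trace, window_start_ms = -105,
                             window_end_ms = -5) {
  stopifnot(inherits(trace, "emg_trace"))
  if (window_end_ms > 0) {
    stop_field("window_end_ms", "background window must end at or before the stimulus")
  }
  if (window_start_ms >= window_end_ms) {
    stop_field("window_start_ms", "must be earlier than window_end_ms")
  }
  i0 <- time_to_index(trace, window_start_ms)
  i1 <- time_to_index(trace, window_end_ms) - 1L  # half-open [start, end)
  if (i0 < 1L) {
    stop_field("window_start_ms", "background window extends past the start of the trace")
  }
  r <- rectify(trace)[i0:i1]
  structure(list(mean_rectified = mean(r),
                 sd_rectified = if (length(r) > 1) sd(r) else 0,
                 window_start = window_start_ms,
                 window_end = window_end_ms),
            class = "background_stats")
}

#' Write / read a single trial
#'
#' A trial is stored as two plain-text files sharing a basename: a CSV with
#' header `time_ms,emg_uV` (one voltage per line, time in ms relative to the
#' stimulus) and a JSON sidecar carrying the metadata, `sampling_rate_hz`
#' and `stimulus_index`. The round trip preserves samples to full precision.
#'
#' @param trace An [emg_trace()].
#' @param path Path to the trial CSV (with or without the `.csv` suffix);
#'   the sidecar uses the same basename with `.json`.
#' @return `write_trial` returns the CSV path invisibly; `read_trial`
#'   returns an [emg_trace()].
#' @export
write_trial <- function(trace, path) {
  stopifnot(inherits(trace, "emg_trace"))
  csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  base <- sub("\\.csv$", "", csv)
  t_ms <- trace_time_ms(trace)
  lines <- c("time_ms,emg_uV",
             sprintf("%s,%s", format(t_ms, trim = TRUE, digits = 15),
                     format(trace$samples, trim = TRUE, digits = 17)))
  writeLines(lines, csv)
  md <- trace$metadata
  sidecar <- list(participant_id = md$participant_id, hand = md$hand,
                  muscle = md$muscle, coil_orientation = md$coil_orientation,
                  task = md$task, timepoint = md$timepoint,
                  stimulus_intensity = md$stimulus_intensity,
                  threshold_type = md$threshold_type,
                  sampling_rate_hz = trace$sampling_rate,
                  stimulus_index = trace$stimulus_index,
                  units = "uV")
  jsonlite::write_json(sidecar, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(csv)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  base <- sub("\\.csv$", "", csv)
  sidecar_path <- paste0(base, ".json")
  if (!file.exists(csv)) stop("trial file not found: ", csv, call. = FALSE)
  if (!file.exists(sidecar_path)) {
    stop("sidecar not found: ", sidecar_path, call. = FALSE)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (field in c("sampling_rate_hz", "stimulus_index")) {
    if (is.null(sc[[field]]) || is.na(suppressWarnings(as.numeric(sc[[field]])))) {
      stop(sprintf("sidecar %s is missing required field '%s'",
                   sidecar_path, field), call. = FALSE)
    }
  }
  lines <- readLines(csv)
  if (length(lines) < 2 || lines[1] != "time_ms,emg_uV") {
    stop("trial CSV must start with header 'time_ms,emg_uV': ", csv,
         call. = FALSE)
  }
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  vals <- suppressWarnings(vapply(parts, function(p) as.numeric(p[2]), 0))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals))[1] + 1L
    stop(sprintf("non-numeric sample at line %d of %s", bad, csv),
         call. = FALSE)
  }
  if (identical(sc$units, "mV")) vals <- vals * 1000
  md <- trial_metadata(
    participant_id = sc$participant_id %||% "unknown",
    hand = sc$hand %||% "contralateral",
    muscle = sc$muscle %||% "FDI",
    coil_orientation = sc$coil_orientation %||% "none",
    task = sc$task %||% "rest",
    timepoint = sc$timepoint %||% "BL",
    stimulus_intensity = sc$stimulus_intensity %||% NA_real_,
    threshold_type = {
      tt <- sc$threshold_type
      if (is.null(tt) || length(tt) != 1 || is.na(tt)) NA_character_
      else as.character(tt)
    })
  emg_trace(vals, sc$sampling_rate_hz, sc$stimulus_index, md)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b
  else a
}
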