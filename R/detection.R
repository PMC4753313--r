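# Per-trial detection of MEP onset/amplitude and of the contralateral and
# ipsilateral silent periods on rectified EMG, using sustained threshold
# criteria expressed in consecutive sampling points (5 ms = 10 points at
# 2 kHz). LTI (latency of transcallosal inhibition) is the iSP onset and
# DTI (duration) is iSP offset minus onset.

#' Detection parameters
#'
#' Threshold and duration criteria for MEP and silent-period detection.
#' Event times are defined by runs of consecutive samples of the rectified
#' signal meeting a level criterion: the 5 ms minimum durations correspond
#' to 10 consecutive sampling points at 2 kHz.
#'
#' @param isp_decline_fraction Fractional decline from the pre-stimulus
#'   background that counts as suppression for the iSP onset (default 0.25,
#'   i.e. rectified EMG at or below 75% of background).
#' @param isp_min_duration_ms Minimum duration of the decline (default 5).
#' @param isp_recovery_min_duration_ms Minimum duration of the sustained
#'   recovery defining the iSP offset, and of the sustained return defining
#'   the cSP offset (default 5).
#' @param csp_return_fraction Fraction of the mean pre-stimulus background
#'   whose return ends the cSP (default 0.5, inclusive).
#' @param mep_onset_k_sd MEP onset threshold in background SDs above the
#'   background mean (default 3).
#' @param mep_onset_sustain_ms The rectified signal must stay above the MEP
#'   threshold for this long (default 1).
#' @param mep_rest_floor_uv Absolute threshold floor in microvolts used when
#'   the background SD is ~0 (rest trials; default 25).
#' @param mep_peak_window_ms Peak-to-peak amplitude is taken over
#'   `[onset, onset + mep_peak_window_ms)` (default 50).
#' @param artifact_blank_ms Post-stimulus interval excluded from every
#'   search, covering the stimulus artifact (default 5).
#' @param search_end_ms Searches stop here; events not found earlier are
#'   reported undetected (default 150).
#' @param smooth_ms Optional causal sliding-mean length applied to the
#'   rectified signal before the run criteria (default 0 = none; the
#'   sustained-run requirement itself is the averaging the criteria call
#'   for).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(isp_decline_fraction = 0.25,
                             isp_min_duration_ms = 5,
                             isp_recovery_min_duration_ms = 5,
                             csp_return_fraction = 0.5,
                             mep_onset_k_sd = 3,
                             mep_onset_sustain_ms = 1,
                             mep_rest_floor_uv = 25,
                             mep_peak_window_ms = 50,
                             artifact_blank_ms = 5,
                             search_end_ms = 150,
                             smooth_ms = 0) {
  check_number(isp_decline_fraction, "isp_decline_fraction",
               lower = 1e-12, upper = 1 - 1e-12)
  check_number(csp_return_fraction, "csp_return_fraction",
               lower = 1e-12, upper = 1 - 1e-12)
  for (f in c("isp_min_duration_ms", "isp_recovery_min_duration_ms",
              "mep_onset_sustain_ms", "mep_peak_window_ms",
              "search_end_ms")) {
    check_number(get(f), f, lower = .Machine$double.eps)
  }
  check_number(mep_onset_k_sd, "mep_onset_k_sd", lower = 0)
  check_number(mep_rest_floor_uv, "mep_rest_floor_uv", lower = 0)
  check_number(artifact_blank_ms, "artifact_blank_ms", lower = 0)
  check_number(smooth_ms, "smooth_ms", lower = 0)
  structure(list(isp_decline_fraction = isp_decline_fraction,
                 isp_min_duration_ms = isp_min_duration_ms,
                 isp_recovery_min_duration_ms = isp_recovery_min_duration_ms,
                 csp_return_fraction = csp_return_fraction,
                 mep_onset_k_sd = mep_onset_k_sd,
                 mep_onset_sustain_ms = mep_onset_sustain_ms,
                 mep_rest_floor_uv = mep_rest_floor_uv,
                 mep_peak_window_ms = mep_peak_window_ms,
                 artifact_blank_ms = artifact_blank_ms,
                 search_end_ms = search_end_ms,
                 smooth_ms = smooth_ms),
            class = "detection_params")
}

#' Convert a duration in ms to a sample count
#'
#' Rounds half up, so the 5 ms criteria equal 10 consecutive sampling
#' points at 2 kHz. The result is never below 1 sample.
#'
#' @param duration_ms Duration in milliseconds (> 0).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @return Integer sample count.
#' @export
ms_to_samples <- function(duration_ms, sampling_rate) {
  check_number(duration_ms, "duration_ms", lower = .Machine$double.eps)
  check_number(sampling_rate, "sampling_rate", lower = .Machine$double.eps)
  max(1L, as.integer(floor(duration_ms * sampling_rate / 1000 + 0.5)))
}

# rectified (optionally smoothed) signal used by all run criteria
detection_signal <- function(trace, params) {
  r <- rectify(trace)
  if (params$smooth_ms > 0) {
    r <- running_mean(r, ms_to_samples(params$smooth_ms,
                                       trace$sampling_rate))
  }
  r
}

search_bounds <- function(trace, params) {
  list(from = time_to_index(trace, params$artifact_blank_ms),
       to = time_to_index(trace, params$search_end_ms))
}

#' Detect MEP onset latency and peak-to-peak amplitude
#'
#' The onset is the earliest post-artifact sample at which the rectified
#' EMG exceeds `background mean + k * SD` and stays above it for
#' `mep_onset_sustain_ms`. On rest trials the background SD is ~0 and an
#' absolute floor (`mep_rest_floor_uv`) applies instead. Amplitude is the
#' max minus min of the raw signal within `mep_peak_window_ms` of onset.
#'
#' @param trace An [emg_trace()].
#' @param bg [background_stats()] computed on the same trace.
#' @param params [detection_params()].
#' @return A list of class `mep_measure` with `onset_latency_ms`,
#'   `amplitude_pp_uv` and `detected`.
#' @export
detect_mep_onset <- function(trace, bg, params = detection_params()) {
  stopifnot(inherits(trace, "emg_trace"), inherits(bg, "background_stats"))
  sig <- detection_signal(trace, params)
  thr <- bg$mean_rectified + params$mep_onset_k_sd * bg$sd_rectified
  if (bg$sd_rectified < 1e-9) thr <- max(thr, params$mep_rest_floor_uv)
  run <- ms_to_samples(params$mep_onset_sustain_ms, trace$sampling_rate)
  b <- search_bounds(trace, params)
  i <- first_sustained_run(sig > thr, run, b$from, b$to)
  if (is.na(i)) {
    return(structure(list(onset_latency_ms = NA_real_,
                          amplitude_pp_uv = NA_real_,
                          detected = FALSE, threshold_uv = thr),
                     class = "mep_measure"))
  }
  j <- min(i + ms_to_samples(params$mep_peak_window_ms,
                             trace$sampling_rate) - 1L,
           length(trace$samples))
  seg <- trace$samples[i:j]
  structure(list(onset_latency_ms = index_to_time(trace, i),
                 amplitude_pp_uv = max(seg) - min(seg),
                 detected = TRUE, threshold_uv = thr),
            class = "mep_measure")
}

#' Detect the contralateral silent period
#'
#' The cSP runs from the MEP onset to the return of at least
#' `csp_return_fraction` (default 50%, inclusive) of the mean pre-stimulus
#' background EMG: after the post-MEP suppression has begun, the offset is
#' the first sample starting a sustained run
#' (`isp_recovery_min_duration_ms`) at or above that level.
#'
#' @param trace Light-contraction trial from the hand contralateral to the
#'   stimulated hemisphere.
#' @param bg [background_stats()] on the same trace; must have a tonic
#'   (non-zero) mean.
#' @param mep The [detect_mep_onset()] result for this trial; must be
#'   detected.
#' @param params [detection_params()].
#' @return A list of class `sp_measure` with `kind = "cSP"`, `onset_ms`
#'   (the MEP onset), `offset_ms`, `duration_ms` and `detected`.
#' @export
detect_csp <- function(trace, bg, mep, params = detection_params()) {
  stopifnot(inherits(trace, "emg_trace"), inherits(bg, "background_stats"))
  if (bg$mean_rectified <= 0) {
    stop("cSP requires tonic background (background mean is zero)",
         call. = FALSE)
  }
  if (!isTRUE(mep$detected)) {
    stop("cSP measurement requires a detected MEP", call. = FALSE)
  }
  sig <- detection_signal(trace, params)
  thr <- params$csp_return_fraction * bg$mean_rectified
  run <- ms_to_samples(params$isp_recovery_min_duration_ms,
                       trace$sampling_rate)
  onset_idx <- time_to_index(trace, mep$onset_latency_ms)
  to <- time_to_index(trace, params$search_end_ms)
  # skip the MEP deflection: silence must begin (a sustained run below the
  # return level; a single sample would fire on the MEP's zero crossing)
  # before a "return" can be looked for
  silence <- first_sustained_run(sig < thr, run, onset_idx, to)
  und <- structure(list(kind = "cSP", onset_ms = mep$onset_latency_ms,
                        offset_ms = NA_real_, duration_ms = NA_real_,
                        detected = FALSE), class = "sp_measure")
  if (is.na(silence)) return(und)
  i <- first_sustained_run(sig >= thr, run, silence, to)
  if (is.na(i)) return(und)
  offset <- index_to_time(trace, i)
  structure(list(kind = "cSP", onset_ms = mep$onset_latency_ms,
                 offset_ms = offset,
                 duration_ms = offset - mep$onset_latency_ms,
                 detected = TRUE),
            class = "sp_measure")
}

#' Detect the ipsilateral silent period (transcallosal inhibition)
#'
#' Onset: the first post-artifact sample starting a run of at least
#' `isp_min_duration_ms` during which the rectified EMG shows a decline of
#' at least `isp_decline_fraction` (default >= 25%) from the pre-stimulus
#' level, i.e. stays at or below `(1 - fraction) * background mean`.
#' Offset: the first subsequent sample starting a sustained recovery
#' (`isp_recovery_min_duration_ms`) above that level. The onset is the
#' latency of transcallosal inhibition (LTI); offset minus onset is its
#' duration (DTI).
#'
#' @param trace Maximum-contraction trial from the hand ipsilateral to the
#'   stimulated hemisphere.
#' @param bg [background_stats()] on the same trace; non-zero mean.
#' @param params [detection_params()].
#' @return A list of class `sp_measure` with `kind = "iSP"`, `onset_ms`,
#'   `offset_ms`, `duration_ms` (= DTI), `lti_ms`, `dti_ms` and `detected`.
#' @export
detect_isp <- function(trace, bg, params = detection_params()) {
  stopifnot(inherits(trace, "emg_trace"), inherits(bg, "background_stats"))
  if (bg$mean_rectified <= 0) {
    stop("iSP requires tonic background (background mean is zero)",
         call. = FALSE)
  }
  sig <- detection_signal(trace, params)
  thr <- (1 - params$isp_decline_fraction) * bg$mean_rectified
  rate <- trace$sampling_rate
  b <- search_bounds(trace, params)
  on_i <- first_sustained_run(sig <= thr, ms_to_samples(
    params$isp_min_duration_ms, rate), b$from, b$to)
  und <- structure(list(kind = "iSP", onset_ms = NA_real_,
                        offset_ms = NA_real_, duration_ms = NA_real_,
                        lti_ms = NA_real_, dti_ms = NA_real_,
                        detected = FALSE), class = "sp_measure")
  if (is.na(on_i)) return(und)
  off_i <- first_sustained_run(sig > thr, ms_to_samples(
    params$isp_recovery_min_duration_ms, rate), on_i + 1L, b$to)
  if (is.na(off_i)) return(und)
  onset <- index_to_time(trace, on_i)
  offset <- index_to_time(trace, off_i)
  structure(list(kind = "iSP", onset_ms = onset, offset_ms = offset,
                 duration_ms = offset - onset,
                 lti_ms = onset, dti_ms = offset - onset,
                 detected = TRUE),
            class = "sp_measure")
}

#' Run the appropriate detectors on one trial
#'
#' Dispatches on the trial's task and hand: rest or orientation trials get
#' MEP detection; contralateral light-contraction trials get MEP + cSP;
#' ipsilateral maximum-contraction trials get iSP.
#'
#' @param trace An [emg_trace()].
#' @param params [detection_params()].
#' @param bg_window Background window in ms relative to the stimulus,
#'   length-2 numeric `c(start, end)`.
#' @return A one-row data.frame (detection-report row) with the trial's
#'   metadata, measures and detected flags.
#' @export
detect_trial <- function(trace, params = detection_params(),
                         bg_window = c(-105, -5)) {
  md <- trace$metadata
  bg <- background_stats(trace, bg_window[1], bg_window[2])
  row <- data.frame(participant_id = md$participant_id, hand = md$hand,
                    muscle = md$muscle,
                    coil_orientation = md$coil_orientation, task = md$task,
                    timepoint = md$timepoint,
                    bg_mean_uv = bg$mean_rectified,
                    bg_sd_uv = bg$sd_rectified,
                    mep_onset_ms = NA_real_, mep_amplitude_uv = NA_real_,
                    mep_detected = NA,
                    sp_kind = NA_character_, sp_onset_ms = NA_real_,
                    sp_offset_ms = NA_real_, sp_duration_ms = NA_real_,
                    sp_detected = NA, stringsAsFactors = FALSE)
  if (md$task == "max_contraction" && md$hand == "ipsilateral") {
    isp <- detect_isp(trace, bg, params)
    row$sp_kind <- "iSP"
    row$sp_onset_ms <- isp$onset_ms
    row$sp_offset_ms <- isp$offset_ms
    row$sp_duration_ms <- isp$duration_ms
    row$sp_detected <- isp$detected
    return(row)
  }
  mep <- detect_mep_onset(trace, bg, params)
  row$mep_onset_ms <- mep$onset_latency_ms
  row$mep_amplitude_uv <- mep$amplitude_pp_uv
  row$mep_detected <- mep$detected
  if (md$task == "light_contraction" && md$hand == "contralateral" &&
      bg$mean_rectified > 0 && mep$detected) {
    csp <- detect_csp(trace, bg, mep, params)
    row$sp_kind <- "cSP"
    row$sp_onset_ms <- csp$onset_ms
    row$sp_offset_ms <- csp$offset_ms
    row$sp_duration_ms <- csp$duration_ms
    row$sp_detected <- csp$detected
  }
  row
}

#' @rdname detect_trial
#' @param traces A list of [emg_trace()] objects.
#' @export
detect_trials <- function(traces, params = detection_params(),
                          bg_window = c(-105, -5)) {
  do.call(rbind, lapply(traces, detect_trial, params = params,
                        bg_window = bg_window))
}

#' Average per-trial measures into per-condition means
#'
#' Arithmetic mean per participant x measure x timepoint over detected
#' trials, with the count of undetected trials reported. Conditions with no
#' detected trial are kept and flagged missing (value `NA`), never silently
#' zero.
#'
#' @param report A detection-report data.frame from [detect_trials()].
#' @return A data.frame with columns `participant_id`, `measure`
#'   (`mep_amplitude`, `mep_onset`, `csp_duration`, `lti`, `dti`),
#'   `timepoint`, `coil_orientation`, `mean_value`, `n_detected`,
#'   `n_undetected`, `missing`.
#' @export
summarize_trials <- function(report) {
  stopifnot(is.data.frame(report))
  pull <- function(value, detected, measure) {
    keep <- !is.na(detected)
    if (!any(keep)) return(NULL)
    df <- report[keep, c("participant_id", "timepoint",
                         "coil_orientation"), drop = FALSE]
    df$value <- value[keep]
    df$detected <- detected[keep]
    df$measure <- measure
    df
  }
  long <- rbind(
    pull(report$mep_amplitude_uv, report$mep_detected, "mep_amplitude"),
    pull(report$mep_onset_ms, report$mep_detected, "mep_onset"),
    pull(ifelse(report$sp_kind %in% "cSP", report$sp_duration_ms, NA),
         ifelse(report$sp_kind %in% "cSP", report$sp_detected, NA),
         "csp_duration"),
    pull(ifelse(report$sp_kind %in% "iSP", report$sp_onset_ms, NA),
         ifelse(report$sp_kind %in% "iSP", report$sp_detected, NA), "lti"),
    pull(ifelse(report$sp_kind %in% "iSP", report$sp_duration_ms, NA),
         ifelse(report$sp_kind %in% "iSP", report$sp_detected, NA), "dti"))
  long <- long[!is.na(long$detected), , drop = FALSE]
  key <- interaction(long$participant_id, long$measure, long$timepoint,
                     long$coil_orientation, drop = TRUE)
  out <- do.call(rbind, lapply(split(long, key), function(g) {
    det <- g$detected
    data.frame(participant_id = g$participant_id[1],
               measure = g$measure[1], timepoint = g$timepoint[1],
               coil_orientation = g$coil_orientation[1],
               mean_value = if (any(det)) mean(g$value[det]) else NA_real_,
               n_detected = sum(det), n_undetected = sum(!det),
               missing = !any(det), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$participant_id, out$measure, out$timepoint), ,
      drop = FALSE]
}
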