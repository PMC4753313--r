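# Synthetic TMS-EMG trials and cohorts with full ground-truth annotation.
#
# The tonic EMG carrier is a deterministic alternating-sign square wave at
# the requested background level, so its rectified mean equals
# `background_level` exactly and event boundaries are sharp; measurement
# noise is added separately via `noise_sd`. Event times recorded in the
# truth annotation are the times as realised on the sample grid.

mep_shape_ms <- 10   # biphasic deflection length (two half-cycles)
mep_decay_ms <- 4    # exponential damping constant

#' Specification of one synthetic EMG trial
#'
#' @param sampling_rate Sampling rate in Hz (default 2000).
#' @param duration_ms Trace length in ms (default 300).
#' @param stimulus_time_ms Stimulus time from trace start in ms (default
#'   110, leaving room for the default 100 ms background window).
#' @param background_level Mean rectified tonic EMG in microvolts; 0 means
#'   rest.
#' @param noise_sd SD of additive Gaussian noise in microvolts.
#' @param mep_onset_ms MEP onset in ms post-stimulus, or `NA` for no MEP.
#' @param mep_amplitude Peak-to-peak MEP amplitude in microvolts.
#' @param sp_onset_ms,sp_offset_ms Silent-period window in ms
#'   post-stimulus (half-open), or `NA` for no suppression.
#' @param sp_depth Fraction of the background retained during suppression,
#'   in `[0, 1]` (0 = complete silence).
#' @param artifact_duration_ms Stimulus-artifact length in ms (default 2).
#' @param artifact_amplitude Artifact peak in microvolts (default 5000).
#' @param metadata [trial_metadata()] attached to the generated trace.
#' @param seed Integer seed driving all randomness for this trace, or
#'   `NULL` to use the current RNG stream.
#' @return A list of class `trace_spec`.
#' @export
trace_spec <- function(sampling_rate = 2000, duration_ms = 300,
                       stimulus_time_ms = 110, background_level = 0,
                       noise_sd = 0, mep_onset_ms = NA, mep_amplitude = NA,
                       sp_onset_ms = NA, sp_offset_ms = NA, sp_depth = 0,
                       artifact_duration_ms = 2, artifact_amplitude = 5000,
                       metadata = trial_metadata(), seed = NULL) {
  check_number(sampling_rate, "sampling_rate", lower = .Machine$double.eps)
  check_number(duration_ms, "duration_ms", lower = .Machine$double.eps)
  check_number(stimulus_time_ms, "stimulus_time_ms", lower = 0,
               upper = duration_ms)
  check_number(background_level, "background_level", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(mep_onset_ms, "mep_onset_ms", lower = 0, allow_na = TRUE)
  check_number(mep_amplitude, "mep_amplitude", lower = 0, allow_na = TRUE)
  check_number(sp_onset_ms, "sp_onset_ms", lower = 0, allow_na = TRUE)
  check_number(sp_offset_ms, "sp_offset_ms", lower = 0, allow_na = TRUE)
  check_number(sp_depth, "sp_depth", lower = 0, upper = 1)
  check_number(artifact_duration_ms, "artifact_duration_ms", lower = 0)
  check_number(artifact_amplitude, "artifact_amplitude", lower = 0)
  if (!is.na(sp_onset_ms) != !is.na(sp_offset_ms)) {
    stop_field("sp_onset_ms/sp_offset_ms",
               "must be given together or both absent")
  }
  if (!is.na(sp_onset_ms) && sp_offset_ms <= sp_onset_ms) {
    stop_field("sp_offset_ms", sprintf(
      "must be greater than sp_onset_ms (%g <= %g)", sp_offset_ms,
      sp_onset_ms))
  }
  if (!is.na(mep_onset_ms) && is.na(mep_amplitude)) {
    stop_field("mep_amplitude", "required when mep_onset_ms is given")
  }
  structure(list(sampling_rate = sampling_rate, duration_ms = duration_ms,
                 stimulus_time_ms = stimulus_time_ms,
                 background_level = background_level, noise_sd = noise_sd,
                 mep_onset_ms = as.numeric(mep_onset_ms),
                 mep_amplitude = as.numeric(mep_amplitude),
                 sp_onset_ms = as.numeric(sp_onset_ms),
                 sp_offset_ms = as.numeric(sp_offset_ms),
                 sp_depth = sp_depth,
                 artifact_duration_ms = artifact_duration_ms,
                 artifact_amplitude = artifact_amplitude,
                 metadata = metadata,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "trace_spec")
}

#' Generate one synthetic EMG trial
#'
#' Renders the tonic background, silent-period suppression, a biphasic MEP
#' deflection, a brief stimulus artifact and additive Gaussian noise, and
#' returns the trace alongside a truth annotation echoing all event times
#' as realised on the sample grid. Identical seeds give bitwise-identical
#' traces.
#'
#' @param spec A [trace_spec()].
#' @return A list with elements `trace` ([emg_trace()]) and `truth`, the
#'   latter holding `mep_onset_ms`, `mep_amplitude`, `sp_onset_ms`,
#'   `sp_offset_ms`, `sp_duration_ms`, `csp_duration_ms` (offset minus MEP
#'   onset, when both exist) and `background_level`.
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  rate <- spec$sampling_rate
  n <- as.integer(round(spec$duration_ms * rate / 1000))
  stim_idx <- as.integer(round(spec$stimulus_time_ms * rate / 1000))
  t_ms <- ((seq_len(n) - 1) - stim_idx) / rate * 1000  # ms post-stimulus

  snap <- function(x) {
    if (is.na(x)) NA_real_ else round(x * rate / 1000) / rate * 1000
  }
  sp_on <- snap(spec$sp_onset_ms)
  sp_off <- snap(spec$sp_offset_ms)
  mep_on <- snap(spec$mep_onset_ms)

  carrier <- spec$background_level * rep_len(c(1, -1), n)
  if (!is.na(sp_on)) {
    inside <- t_ms >= sp_on & t_ms < sp_off
    carrier[inside] <- carrier[inside] * spec$sp_depth
  }
  x <- carrier

  if (!is.na(mep_on)) {
    tau <- t_ms - mep_on
    in_mep <- tau >= 0 & tau < mep_shape_ms
    w <- numeric(n)
    # small phase lead so the deflection departs from baseline at the
    # onset sample itself (MEP rise is steep); shape stays biphasic
    w[in_mep] <- sin(2 * pi * (tau[in_mep] + 0.5) / mep_shape_ms) *
      exp(-tau[in_mep] / mep_decay_ms)
    pp <- max(w) - min(w)
    if (pp > 0) x <- x + w * (spec$mep_amplitude / pp)
  }

  if (spec$artifact_duration_ms > 0 && spec$artifact_amplitude > 0) {
    in_art <- t_ms >= 0 & t_ms < spec$artifact_duration_ms
    k <- which(in_art)
    if (length(k)) {
      ramp <- 1 - (t_ms[k] / spec$artifact_duration_ms)
      x[k] <- x[k] + spec$artifact_amplitude * ramp *
        rep_len(c(1, -1), length(k))
    }
  }

  if (spec$noise_sd > 0) {
    x <- x + with_seed(spec$seed, rnorm(n, 0, spec$noise_sd))
  }

  trace <- emg_trace(x, rate, stim_idx, spec$metadata)
  truth <- list(mep_onset_ms = mep_on, mep_amplitude = spec$mep_amplitude,
                sp_onset_ms = sp_on, sp_offset_ms = sp_off,
                sp_duration_ms = if (is.na(sp_on)) NA_real_
                                 else sp_off - sp_on,
                csp_duration_ms = if (is.na(sp_off) || is.na(mep_on))
                                    NA_real_ else sp_off - mep_on,
                background_level = spec$background_level,
                sp_depth = spec$sp_depth)
  list(trace = trace, truth = truth)
}

#' Specification of a synthetic cohort
#'
#' Describes the generative model for a whole study: per-participant coil
#' orientation latencies, a linear link from the AP-LM latency difference
#' to the MEP response ratio, and per-measure baseline distributions with
#' per-timepoint multiplicative after-effects. Defaults describe a cohort
#' of 20 with group orientation latencies LM 19.4, PA 20.8 and AP 22.0 ms,
#' a consistent LTI reduction and DTI prolongation after stimulation, and
#' no cSP after-effect.
#'
#' @param n_participants Number of participants (>= 2; default 20).
#' @param true_slope,true_intercept Linear link from the AP-LM latency
#'   difference (ms) to the MEP response ratio (defaults -0.2 and 1.5: a
#'   participant with a 2.5 ms difference is at ratio 1).
#' @param predictor_range Length-2 range (ms) of the uniform AP-LM latency
#'   difference distribution (default `c(0.5, 4.5)`).
#' @param residual_sd SD of the ratio noise around the linear link
#'   (default 0.15).
#' @param lm_latency_mean,lm_latency_sd LM onset latency distribution in
#'   ms (defaults 19.4 and 1.5).
#' @param pa_lm_range Range (ms) of the uniform PA-LM latency difference
#'   (default `c(0.4, 2.4)`).
#' @param measures Named list (`mep`, `csp`, `lti`, `dti`); each element a
#'   list with `bl_mean`, `bl_sd` (baseline distribution across
#'   participants), `effects` (named numeric of true multiplicative
#'   effects at the measure's post timepoints) and `measurement_cv`
#'   (within-participant session-to-session coefficient of variation,
#'   applied at every timepoint including baseline).
#' @param seed Integer seed, or `NULL`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 20, true_slope = -0.2,
                        true_intercept = 1.5,
                        predictor_range = c(0.5, 4.5), residual_sd = 0.15,
                        lm_latency_mean = 19.4, lm_latency_sd = 1.5,
                        pa_lm_range = c(0.4, 2.4),
                        measures = cohort_measures(), seed = NULL) {
  check_number(n_participants, "n_participants", lower = 2)
  check_number(residual_sd, "residual_sd", lower = 0)
  check_number(true_slope, "true_slope")
  check_number(true_intercept, "true_intercept")
  stopifnot(length(predictor_range) == 2, diff(predictor_range) >= 0,
            length(pa_lm_range) == 2)
  needed <- c("mep", "csp", "lti", "dti")
  if (!all(needed %in% names(measures))) {
    stop_field("measures", paste("must contain",
                                 paste(needed, collapse = ", ")))
  }
  structure(list(n_participants = as.integer(n_participants),
                 true_slope = true_slope, true_intercept = true_intercept,
                 predictor_range = predictor_range,
                 residual_sd = residual_sd,
                 lm_latency_mean = lm_latency_mean,
                 lm_latency_sd = lm_latency_sd, pa_lm_range = pa_lm_range,
                 measures = measures,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param mep,csp,lti,dti Per-measure settings; see `measures` above.
#'   Baseline defaults: resting MEP amplitude 1000 +/- 400 uV, cSP
#'   duration 120 +/- 25 ms, LTI 35 +/- 4 ms, DTI 25 +/- 6 ms. Effect
#'   defaults: no true cSP change, LTI reduced by 5% and DTI prolonged by
#'   10% at both post timepoints.
#' @export
cohort_measures <- function(
    mep = list(bl_mean = 1000, bl_sd = 400,
               effects = c(T10 = NA, T20 = NA),  # driven by the predictor link
               measurement_cv = 0.15),
    csp = list(bl_mean = 120, bl_sd = 25, effects = c(T20 = 1, T40 = 1),
               measurement_cv = 0.05),
    lti = list(bl_mean = 35, bl_sd = 4, effects = c(T20 = 0.95, T40 = 0.95),
               measurement_cv = 0.03),
    dti = list(bl_mean = 25, bl_sd = 6, effects = c(T20 = 1.10, T40 = 1.10),
               measurement_cv = 0.06)) {
  list(mep = mep, csp = csp, lti = lti, dti = dti)
}

#' Generate a synthetic cohort (record level)
#'
#' Draws per-participant orientation latencies and predictor values, then
#' per-measure values at baseline and the post timepoints such that the
#' participant's MEP response ratio follows
#' `intercept + slope * (AP-LM difference) + noise` and the other measures
#' follow their configured multiplicative effects. Returns one row per
#' participant plus the ground truth.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `records` (data.frame, one row per participant:
#'   orientation latencies and differences, and `mep_bl/t10/t20`,
#'   `csp_bl/t20/t40`, `lti_bl/t20/t40`, `dti_bl/t20/t40`) and `truth`
#'   (slope, intercept, per-participant predictors and target ratios,
#'   per-measure effects).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  with_seed(spec$seed, {
    lm_lat <- rnorm(n, spec$lm_latency_mean, spec$lm_latency_sd)
    ap_lm <- runif(n, spec$predictor_range[1], spec$predictor_range[2])
    pa_lm <- runif(n, spec$pa_lm_range[1], spec$pa_lm_range[2])
    pa_lat <- lm_lat + pa_lm
    ap_lat <- lm_lat + ap_lm

    target_ratio <- spec$true_intercept + spec$true_slope * ap_lm +
      (if (spec$residual_sd > 0) rnorm(n, 0, spec$residual_sd) else 0)
    target_ratio <- pmax(target_ratio, 0.05)

    draw_bl <- function(m) pmax(rnorm(n, m$bl_mean, m$bl_sd),
                                0.05 * m$bl_mean)
    noisy <- function(true, cv) {
      if (cv > 0) true * pmax(1 + rnorm(n, 0, cv), 0.05) else true
    }
    ms <- spec$measures

    mep_true <- draw_bl(ms$mep)
    records <- data.frame(
      participant_id = sprintf("P%02d", seq_len(n)),
      pa_ms = pa_lat, lm_ms = lm_lat, ap_ms = ap_lat,
      ap_lm_ms = ap_lm, pa_lm_ms = pa_lm, ap_pa_ms = ap_lm - pa_lm,
      mep_bl = noisy(mep_true, ms$mep$measurement_cv),
      mep_t10 = noisy(mep_true * target_ratio, ms$mep$measurement_cv),
      mep_t20 = noisy(mep_true * target_ratio, ms$mep$measurement_cv),
      stringsAsFactors = FALSE)

    for (nm in c("csp", "lti", "dti")) {
      m <- ms[[nm]]
      true <- draw_bl(m)
      records[[paste0(nm, "_bl")]] <- noisy(true, m$measurement_cv)
      for (tp in names(m$effects)) {
        records[[paste0(nm, "_", tolower(tp))]] <-
          noisy(true * m$effects[[tp]], m$measurement_cv)
      }
    }

    list(records = records,
         truth = list(true_slope = spec$true_slope,
                      true_intercept = spec$true_intercept,
                      predictor_ap_lm = ap_lm,
                      target_mep_ratio = target_ratio,
                      effects = lapply(ms, `[[`, "effects")))
  })
}

#' Render a cohort's records as per-trial synthetic traces
#'
#' Expands record-level values into the full trial structure of the
#' paradigm: per orientation, 10 active-contraction MEP trials; per MEP
#' timepoint (BL/T10/T20), 10 resting MEP trials; per silent-period
#' timepoint (BL/T20/T40), 5 paired contraction trials (contralateral
#' light contraction carrying the MEP + cSP, ipsilateral maximum
#' contraction carrying the iSP).
#'
#' @param cohort Result of [generate_cohort()].
#' @param n_orientation_trials,n_mep_trials,n_sp_trials Trials per
#'   condition (defaults 10, 10, 5).
#' @param noise_sd Additive noise in microvolts (default 10; 0 gives fully
#'   deterministic traces).
#' @param trial_jitter_cv Trial-to-trial coefficient of variation applied
#'   to amplitudes and durations (default 0.05; 0 disables).
#' @param latency_jitter_ms SD of trial-to-trial onset-latency jitter
#'   (default 0.3; 0 disables).
#' @param light_bg_uv,max_bg_uv Tonic background during light and maximum
#'   contraction (defaults 100 and 200 uV).
#' @param sp_depth Background fraction retained inside silent periods
#'   (default 0.1).
#' @param seed Integer seed, or `NULL`.
#' @return A list with `traces` (list of [emg_trace()]) and `truths`
#'   (data.frame of per-trial realised event times).
#' @export
cohort_trials <- function(cohort, n_orientation_trials = 10,
                          n_mep_trials = 10, n_sp_trials = 5,
                          noise_sd = 10, trial_jitter_cv = 0.05,
                          latency_jitter_ms = 0.3, light_bg_uv = 100,
                          max_bg_uv = 200, sp_depth = 0.1, seed = NULL) {
  records <- cohort$records
  traces <- list()
  truths <- list()
  k <- 0L
  with_seed(seed, {
    jit_cv <- function(x) if (trial_jitter_cv > 0)
      x * pmax(1 + rnorm(1, 0, trial_jitter_cv), 0.05) else x
    jit_ms <- function(x) if (latency_jitter_ms > 0)
      max(x + rnorm(1, 0, latency_jitter_ms), 1) else x
    push <- function(sp, info) {
      g <- generate_trace(sp)
      k <<- k + 1L
      traces[[k]] <<- g$trace
      truths[[k]] <<- cbind(info, as.data.frame(g$truth))
    }
    for (i in seq_len(nrow(records))) {
      r <- records[i, ]
      pid <- r$participant_id
      for (ori in c("PA", "LM", "AP")) {
        lat <- r[[paste0(tolower(ori), "_ms")]]
        for (tr in seq_len(n_orientation_trials)) {
          md <- trial_metadata(pid, hand = "contralateral",
                               coil_orientation = ori,
                               task = "light_contraction",
                               timepoint = "BL",
                               stimulus_intensity = if (ori == "PA") 110
                                                    else 140,
                               threshold_type = "aMT")
          push(trace_spec(background_level = light_bg_uv,
                          noise_sd = noise_sd,
                          mep_onset_ms = jit_ms(lat),
                          mep_amplitude = jit_cv(800),
                          metadata = md, seed = NULL),
               data.frame(participant_id = pid, condition = "orientation",
                          coil_orientation = ori, timepoint = "BL"))
        }
      }
      for (tp in c("BL", "T10", "T20")) {
        amp <- r[[paste0("mep_", tolower(tp))]]
        for (tr in seq_len(n_mep_trials)) {
          md <- trial_metadata(pid, hand = "contralateral",
                               coil_orientation = "PA", task = "rest",
                               timepoint = tp, stimulus_intensity = 120,
                               threshold_type = "rMT")
          push(trace_spec(background_level = 0, noise_sd = noise_sd,
                          mep_onset_ms = jit_ms(22),
                          mep_amplitude = jit_cv(amp),
                          metadata = md, seed = NULL),
               data.frame(participant_id = pid, condition = "rest_mep",
                          coil_orientation = "PA", timepoint = tp))
        }
      }
      for (tp in c("BL", "T20", "T40")) {
        csp_d <- r[[paste0("csp_", tolower(tp))]]
        lti <- r[[paste0("lti_", tolower(tp))]]
        dti <- r[[paste0("dti_", tolower(tp))]]
        for (tr in seq_len(n_sp_trials)) {
          mep_on <- jit_ms(r$pa_ms)
          dur <- jit_cv(csp_d)
          md_c <- trial_metadata(pid, hand = "contralateral",
                                 coil_orientation = "PA",
                                 task = "light_contraction",
                                 timepoint = tp, stimulus_intensity = 130,
                                 threshold_type = "rMT")
          push(trace_spec(duration_ms = 330, background_level = light_bg_uv,
                          noise_sd = noise_sd, mep_onset_ms = mep_on,
                          mep_amplitude = jit_cv(1500),
                          sp_onset_ms = mep_on + mep_shape_ms,
                          sp_offset_ms = mep_on + max(dur,
                                                      mep_shape_ms + 5),
                          sp_depth = sp_depth, metadata = md_c,
                          seed = NULL),
               data.frame(participant_id = pid, condition = "csp",
                          coil_orientation = "PA", timepoint = tp))
          on <- jit_ms(lti)
          md_i <- trial_metadata(pid, hand = "ipsilateral",
                                 coil_orientation = "PA",
                                 task = "max_contraction",
                                 timepoint = tp, stimulus_intensity = 130,
                                 threshold_type = "rMT")
          push(trace_spec(background_level = max_bg_uv,
                          noise_sd = noise_sd, sp_onset_ms = on,
                          sp_offset_ms = on + max(jit_cv(dti), 5),
                          sp_depth = sp_depth, metadata = md_i,
                          seed = NULL),
               data.frame(participant_id = pid, condition = "isp",
                          coil_orientation = "PA", timepoint = tp))
        }
      }
    }
  })
  list(traces = traces, truths = do.call(rbind, truths))
}
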