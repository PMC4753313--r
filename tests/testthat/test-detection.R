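make_trace <- function(samples, rate = 2000, stim = 0, task = "rest",
                       hand = "contralateral") {
  emg_trace(samples, rate, stim,
            trial_metadata(task = task, hand = hand))
}

test_that("ms_to_samples rounds half up and validates", {
  expect_identical(ms_to_samples(5, 2000), 10L)
  expect_identical(ms_to_samples(0.5, 2000), 1L)
  expect_identical(ms_to_samples(5, 1000), 5L)
  expect_identical(ms_to_samples(1.25, 2000), 3L)  # 2.5 rounds up
  expect_error(ms_to_samples(0, 2000), "duration_ms")
  expect_error(ms_to_samples(5, -1), "sampling_rate")
})

test_that("MEP onset detection on constructed traces", {
  # flat trace: nothing to detect
  tr <- make_trace(rep(0, 400), stim = 200)
  expect_false(detect_mep_onset(tr, background_stats(tr, -100, 0))$detected)

  # noiseless step from 0 to 500 uV, 40 samples (20 ms at 2 kHz) after
  # the stimulus
  x <- rep(0, 400); x[(201 + 40):400] <- 500
  tr <- make_trace(x, stim = 200)
  mep <- detect_mep_onset(tr, background_stats(tr, -100, 0))
  expect_true(mep$detected)
  expect_equal(mep$onset_latency_ms, 20)
})

test_that("MEP onset recovery on noisy generated traces", {
  set.seed(21)
  errs <- vapply(1:60, function(i) {
    g <- generate_trace(trace_spec(background_level = 100, noise_sd = 15,
                                   mep_onset_ms = runif(1, 18, 25),
                                   mep_amplitude = 1000))
    m <- detect_mep_onset(g$trace, background_stats(g$trace))
    abs(m$onset_latency_ms - g$truth$mep_onset_ms)
  }, 0)
  expect_true(all(is.finite(errs)))
  expect_lte(mean(errs), 0.5)
})

test_that("cSP offset is the sustained return of >= 50% background", {
  # bg 100, MEP onset 20 ms, silence over [30, 120), full background after
  g <- generate_trace(trace_spec(background_level = 100, noise_sd = 0,
                                 mep_onset_ms = 20, mep_amplitude = 1500,
                                 sp_onset_ms = 30, sp_offset_ms = 120,
                                 sp_depth = 0))
  bg <- background_stats(g$trace)
  mep <- detect_mep_onset(g$trace, bg)
  csp <- detect_csp(g$trace, bg, mep)
  expect_true(csp$detected)
  expect_equal(csp$offset_ms, 120)
  expect_equal(csp$duration_ms, 120 - mep$onset_latency_ms)

  # no recovery within the search window -> undetected
  g2 <- generate_trace(trace_spec(background_level = 100, noise_sd = 0,
                                  mep_onset_ms = 20, mep_amplitude = 1500,
                                  sp_onset_ms = 30, sp_offset_ms = 185,
                                  sp_depth = 0))
  csp2 <- detect_csp(g2$trace, bg, detect_mep_onset(g2$trace, bg))
  expect_false(csp2$detected)

  expect_error(
    detect_csp(make_trace(rep(0, 700), stim = 300),
               background_stats(make_trace(rep(0, 700), stim = 300)), mep),
    "tonic background")
})

test_that("a return at exactly 50% of background qualifies (inclusive)", {
  rate <- 2000
  x <- rep(c(100, -100), 350)           # tonic +/-100, stim at sample 300
  t_ms <- ((seq_along(x) - 1) - 300) / rate * 1000
  x[t_ms >= 15 & t_ms < 25] <- 600      # MEP-like burst at 15 ms
  x[t_ms >= 25 & t_ms < 80] <- 0        # silence
  x[t_ms >= 80] <- rep_len(c(50, -50), sum(t_ms >= 80))  # exactly 50%
  tr <- make_trace(x, stim = 300, task = "light_contraction")
  bg <- background_stats(tr)
  mep <- detect_mep_onset(tr, bg)
  csp <- detect_csp(tr, bg, mep, detection_params())
  expect_true(csp$detected)
  expect_equal(csp$offset_ms, 80)
})

test_that("iSP onset/offset on noiseless construction are exact", {
  g <- generate_trace(trace_spec(background_level = 100, noise_sd = 0,
                                 sp_onset_ms = 30, sp_offset_ms = 60,
                                 sp_depth = 0))
  isp <- detect_isp(g$trace, background_stats(g$trace))
  expect_true(isp$detected)
  expect_equal(isp$onset_ms, 30)
  expect_equal(isp$offset_ms, 60)
  expect_equal(isp$dti_ms, 30)
  expect_equal(isp$lti_ms, isp$onset_ms)

  flat <- generate_trace(trace_spec(background_level = 100, noise_sd = 0))
  expect_false(detect_isp(flat$trace,
                          background_stats(flat$trace))$detected)
  rest <- make_trace(rep(0, 700), stim = 300)
  expect_error(detect_isp(rest, background_stats(rest)),
               "tonic background")
})

test_that("iSP recovery on noisy generated traces", {
  set.seed(31)
  err_on <- err_off <- numeric(60)
  for (i in 1:60) {
    on <- runif(1, 25, 40); dur <- runif(1, 15, 40)
    g <- generate_trace(trace_spec(background_level = 200, noise_sd = 20,
                                   sp_onset_ms = on, sp_offset_ms = on + dur,
                                   sp_depth = 0.2))
    d <- detect_isp(g$trace, background_stats(g$trace))
    err_on[i] <- abs(d$onset_ms - g$truth$sp_onset_ms)
    err_off[i] <- abs(d$offset_ms - g$truth$sp_offset_ms)
  }
  expect_lte(median(err_on), 1)
  expect_lte(median(err_off), 1)
})

test_that("detectors agree with the exhaustive window-scan oracle", {
  set.seed(55)
  for (i in 1:30) {
    # random noisy trace with a random (possibly absent) suppression
    has_sp <- i %% 3 != 0
    on <- runif(1, 10, 60); dur <- runif(1, 6, 50)
    sp <- trace_spec(background_level = runif(1, 60, 250),
                     noise_sd = runif(1, 5, 60),
                     sp_onset_ms = if (has_sp) on else NA,
                     sp_offset_ms = if (has_sp) on + dur else NA,
                     sp_depth = runif(1, 0, 0.6), seed = 1000 + i)
    g <- generate_trace(sp)
    bg <- background_stats(g$trace)
    d <- detect_isp(g$trace, bg)
    o <- oracle_isp_indices(g$trace$samples, g$trace$stimulus_index,
                            g$trace$sampling_rate, bg$mean_rectified)
    if (is.na(o$onset) || is.na(o$offset)) {
      expect_false(d$detected)
    } else {
      expect_true(d$detected)
      expect_equal(d$onset_ms,
                   (o$onset - 1 - g$trace$stimulus_index) / 2)
      expect_equal(d$offset_ms,
                   (o$offset - 1 - g$trace$stimulus_index) / 2)
    }
  }
})

test_that("deeper required declines never give earlier onsets (monotonicity)", {
  set.seed(77)
  for (i in 1:10) {
    g <- generate_trace(trace_spec(background_level = 150,
                                   noise_sd = 40, sp_onset_ms = 35,
                                   sp_offset_ms = 70,
                                   sp_depth = runif(1, 0.1, 0.5),
                                   seed = i))
    bg <- background_stats(g$trace)
    onsets <- vapply(c(0.15, 0.25, 0.4, 0.6), function(f) {
      d <- detect_isp(g$trace, bg,
                      detection_params(isp_decline_fraction = f))
      if (d$detected) d$onset_ms else Inf
    }, 0)
    expect_false(is.unsorted(onsets))  # undetected counts as +Inf
  }
})

test_that("latencies are equivariant under joint time shifts", {
  base <- generate_trace(trace_spec(background_level = 120, noise_sd = 10,
                                    sp_onset_ms = 33, sp_offset_ms = 61,
                                    sp_depth = 0.1, seed = 9))$trace
  shift <- 40L
  shifted <- emg_trace(c(rep(c(120, -120), shift / 2), base$samples),
                       base$sampling_rate, base$stimulus_index + shift,
                       base$metadata)
  a <- detect_isp(base, background_stats(base))
  b <- detect_isp(shifted, background_stats(shifted))
  expect_equal(a$onset_ms, b$onset_ms)
  expect_equal(a$offset_ms, b$offset_ms)
})

test_that("duration identities hold for every detection", {
  set.seed(13)
  for (i in 1:10) {
    g <- generate_trace(trace_spec(background_level = 180, noise_sd = 25,
                                   sp_onset_ms = runif(1, 25, 45),
                                   sp_offset_ms = runif(1, 55, 90),
                                   sp_depth = 0.15))
    d <- detect_isp(g$trace, background_stats(g$trace))
    if (d$detected) {
      expect_equal(d$duration_ms, d$offset_ms - d$onset_ms)
      expect_equal(d$dti_ms, d$offset_ms - d$lti_ms)
    }
  }
})

test_that("summarize_trials averages detected trials and flags missing", {
  rep3 <- do.call(rbind, lapply(c(1, 2, 3), function(a) {
    r <- detect_trial(generate_trace(trace_spec(
      background_level = 0, noise_sd = 0, mep_onset_ms = 22,
      mep_amplitude = a * 100))$trace)
    r
  }))
  s <- summarize_trials(rep3)
  amp <- s[s$measure == "mep_amplitude", ]
  expect_equal(amp$mean_value, 200)
  expect_equal(amp$n_detected, 3)

  # one undetected among four trials
  flat <- detect_trial(generate_trace(trace_spec(background_level = 0,
                                                 noise_sd = 0))$trace)
  s2 <- summarize_trials(rbind(rep3, flat))
  amp2 <- s2[s2$measure == "mep_amplitude", ]
  expect_equal(amp2$mean_value, 200)
  expect_equal(amp2$n_undetected, 1)
  expect_false(amp2$missing)

  # zero detected trials -> flagged missing, not zero
  s3 <- summarize_trials(flat)
  expect_true(s3[s3$measure == "mep_amplitude", "missing"])
  expect_true(is.na(s3[s3$measure == "mep_amplitude", "mean_value"]))
})
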