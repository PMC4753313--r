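---
title: "Detecting silent periods and MEPs in TMS-EMG, and the cohort statistics behind tDCS after-effect studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tmsemg methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsemg)
```

## The problem

Single-pulse transcranial magnetic stimulation (TMS) over the primary motor
cortex evokes a motor evoked potential (MEP) in a contralateral hand muscle,
recorded with surface EMG (here nominally digitized at 2 kHz). When the
target muscle is voluntarily contracting, the MEP is followed by a
*contralateral silent period* (cSP) — a transient suppression of voluntary
EMG linked to GABA-B intracortical inhibition. Stimulating the hemisphere
*ipsilateral* to a maximally contracting hand instead produces an
*ipsilateral silent period* (iSP), a brief dip in ongoing EMG mediated by
transcallosal inhibition. The iSP onset indexes the latency of transcallosal
inhibition (LTI) and offset minus onset its duration (DTI).

Neuromodulation studies (e.g. anodal transcranial direct current
stimulation, a-tDCS) quantify after-effects by comparing these measures
before (BL) and at fixed times after the intervention (T10/T20/T40), and ask
whether inter-individual variability in the response can be predicted from
TMS coil-orientation latency differences: MEPs elicited with latero-medial
(LM) induced current have the shortest onset latency (direct-wave
recruitment), posterior-anterior (PA) current recruits early indirect waves
and anterior-posterior (AP) current late indirect waves. The per-participant
AP−LM and PA−LM onset-latency differences are therefore surrogate measures
of how easily late vs. early I-waves are recruited, and small differences
predict "canonical" facilitation after a-tDCS.

`tmsemg` implements this analysis end to end: a synthetic trial/cohort
generator with ground truth, trial IO, per-trial detection, per-participant
latency predictors, and the cohort statistics.

## Detection rules

All detection operates on the full-wave rectified signal, against the
*pre-stimulus background*: the mean (and SD) of rectified EMG over a window
defaulting to [−105, −5) ms relative to the pulse. The window ends 5 ms
before the pulse to avoid pre-trigger artifacts; its exact placement was not
prescribed by the source protocols, so it is configurable.

* **MEP onset** — earliest post-artifact sample at which rectified EMG
  exceeds `background mean + 3 SD` and stays above it for 1 ms. On rest
  trials the background SD is ≈ 0 and a 25 µV absolute floor applies. This
  automates what is traditionally done by visual inspection; the recovery
  tests bound its error. Amplitude is peak-to-peak over the 50 ms following
  onset.
* **iSP onset** — first post-artifact sample starting a run of at least
  5 ms during which rectified EMG sits at or below 75% of the background
  mean (a decline of ≥ 25%, inclusive). At 2 kHz the 5 ms criterion is
  exactly 10 consecutive sampling points.
* **iSP offset** — first subsequent sample starting a sustained (> 5 ms)
  run back above that level. The recovery level is chosen as the complement
  of the onset criterion; the field's descriptions say only "sustained
  recovery", so this is a package design choice, exposed as
  `isp_decline_fraction`.
* **cSP offset** — after the MEP, the first sample starting a sustained
  (5 ms) run at or above 50% of the background mean (inclusive "at least
  50%"). cSP duration is measured from the *MEP onset* to this return.

Two numerical choices deserve emphasis:

1. **Runs of samples, not sliding means.** The duration criteria are
   implemented as runs of consecutive samples satisfying the level
   criterion — the literal "10 consecutive sampling points" reading. An
   alternative operationalization (a 5 ms sliding mean crossing the
   threshold) systematically anticipates sharp boundaries by up to a
   quarter window, which breaks exact recovery of constructed events; it is
   still available as an optional causal pre-smoother (`smooth_ms`,
   default 0, i.e. off).
2. **Sustained silence before the cSP return.** The search for the EMG
   return begins only once a sustained sub-threshold run has been seen
   after the MEP onset; a single sub-threshold sample would trigger on the
   biphasic MEP's zero crossing and terminate the cSP inside the MEP
   itself.

Ties are broken toward the earliest evidence: every event time is the first
sample of the first qualifying run. Comparisons at thresholds are inclusive
("at least"). Undetected events are flagged, never coerced to zero, and
per-condition averaging reports the number of undetected trials.

## The synthetic generator

No raw recordings accompany the analysis this package operationalizes, so
the generator is the test bed. One trial is composed of:

* a **tonic carrier**: a deterministic alternating-sign square wave whose
  rectified mean equals `background_level` *exactly*. A Gaussian tonic
  background (rectified mean calibrated via √(π/2)) was considered and
  rejected: even "noiseless" Gaussian EMG produces occasional sustained
  sub-threshold runs before a true suppression onset, so the generator
  could not guarantee its own ground truth to within one sample.
  Stochasticity is instead injected explicitly through `noise_sd` additive
  Gaussian noise, which is what the recovery tests exercise;
* a **silent period**: the carrier scaled by `sp_depth` inside
  [`sp_onset`, `sp_offset`) (0 = complete silence);
* an **MEP**: a damped biphasic sinusoid (two half-cycles over ~10 ms,
   4 ms decay constant) scaled to the requested peak-to-peak amplitude. The
  waveform is rendered with a small phase lead so its first sample already
  departs from baseline: with a zero-valued onset sample, any threshold
  detector is one sample late by construction and the onset-error budget
  would measure the waveform, not the detector;
* a **stimulus artifact**: a large decaying alternating deflection over the
  first 2 ms, which the 5 ms artifact blanking must ignore;
* additive Gaussian **noise**.

All event times recorded in the truth annotation are as realised on the
sample grid. A single integer seed drives each trace; equal seeds give
bitwise-identical traces.

At the cohort level the generator states a world of 20 participants: LM
onset latency ~ N(19.4, 1.5²) ms with AP−LM differences uniform on
[0.5, 4.5] ms and PA−LM on [0.4, 2.4] ms; baseline resting MEP amplitude
1000 ± 400 µV, cSP duration 120 ± 25 ms, LTI 35 ± 4 ms, DTI 25 ± 6 ms
(field-typical values; the source results report only group latencies and
ratios). The MEP response ratio follows
`intercept + slope × (AP−LM) + N(0, residual_sd)` with defaults 1.5, −0.2
and 0.15, so a participant at a 2.5 ms AP−LM difference is response-neutral
— mirroring the observation that differences below ~2.5 ms predict
facilitation. True after-effects default to a consistent 5% LTI reduction
and 10% DTI prolongation at both post timepoints and no cSP change.
Session-to-session measurement noise (multiplicative CV: 15% MEP, 5% cSP,
3% LTI, 6% DTI) applies at *every* timepoint including baseline; without
baseline noise the null repeated-measures ANOVA would not be calibrated
(the baseline column would be error-free, violating compound symmetry).

What a green test establishes, and what it does not: the generator shares
the detectors' signal model (threshold-crossing events on rectified EMG),
so recovery tests validate the *rules*, not robustness to everything real
EMG does — motor-unit structure, pre-innervation drifts, movement
artifacts, line noise and amplifier nonlinearity are all absent by design.

## Statistics

* **Response ratio** — per participant, the grand mean of a measure's post
  values divided by baseline.
* **Grubbs screening** — two-sided single-outlier test on the vector of
  MEP response ratios, `Z = max|x − x̄|/SD` against the t-based critical
  value at α/(2n). A flagged participant is removed from the MEP analyses
  only (ANOVA and regressions with an MEP response), not from cSP/iSP —
  mirroring a single-outlier exclusion policy.
* **Normality policy** — Shapiro–Wilk on the measure's pooled values;
  natural log applied iff p < 0.05 (MEP amplitudes are right-skewed and
  typically require it). The transform flag is recorded.
* **RM-ANOVA** — classical one-way within-subject sums of squares,
  `F = MS_time/MS_error` on (k−1, (k−1)(n−1)) degrees of freedom, listwise
  deletion of incomplete participants. Note that published F statistics in
  this literature sometimes carry df like (2, 19) for n = 20, k = 3, which
  no classical RM-ANOVA produces; this package reports the classical
  (2, 38) and makes no attempt to reverse-engineer other software.
* **Dunnett many-to-one** — each post timepoint vs baseline,
  `t_i = (m_i − m_BL)/√(2·MS_error/n)`, two-sided p-values adjusted under
  the equicorrelated (ρ = ½) multivariate-t distribution on the ANOVA
  error df. The distribution function is computed by nested quadrature
  over the shared χ scale and the common normal factor; a seeded
  Monte-Carlo implementation exists independently and the tests require
  the two to agree to < 0.01 on the critical value. With one comparison
  the adjustment reduces exactly to the unadjusted paired p. If
  `MS_error = 0` the comparisons degenerate to exact equality checks,
  reported as such.
* **Predictor grid** — OLS of each response ratio (MEP, cSP, LTI, DTI) on
  each predictor (baseline MEP, AP−LM, PA−LM, AP−PA), reporting slope,
  intercept, r², p and n; zero-variance predictors are flagged rather than
  fit.

## Pipeline and reproducibility

`tmsemg_cli()` exposes `simulate | detect | analyze | report` with a JSON
config (unknown keys rejected), `--seed/--alpha/--in/--out` overrides, and
exit codes 0/2/3 (success / config error / data error). Every output file
is stamped with the package version, seed and an FNV-1a hash of the
configuration. Trials live as `time_ms,emg_uV` CSVs with JSON sidecars;
write-then-read round trips preserve samples to full precision.

One deliberate configuration asymmetry: the module-level default search
window ends at 150 ms post-stimulus, but the pipeline config extends it to
200 ms (with 330 ms silent-period traces) because realistic cSP offsets —
baseline duration ~120 ± 25 ms measured from an MEP onset near 20 ms —
routinely fall beyond 150 ms and would otherwise be censored.

## Known limitations

* The iSP offset recovery level (75% of background) and the sustained cSP
  return are package choices where the field's verbal descriptions are
  silent; both are parameters, not claims about any author's intent.
* Detection latencies are quantized to the sample grid (0.5 ms at 2 kHz).
* No digital pre-filtering is applied by default; hardware filtering is
  assumed upstream.
* The generator does not model motoneuron-pool physiology, tDCS current
  flow, or sham conditions; statistical power claims transfer to real data
  only insofar as the stated noise magnitudes do.
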