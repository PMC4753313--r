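# tmsemg

Automated analysis of TMS-evoked surface EMG responses around a
neuromodulatory intervention (anodal tDCS): per-trial detection of motor
evoked potentials (MEPs) and of the contralateral/ipsilateral silent
periods (cSP/iSP) on rectified EMG, derivation of transcallosal-inhibition
indices (LTI = iSP onset latency, DTI = iSP offset − onset) and of
coil-orientation latency-difference predictors (AP−LM, PA−LM, AP−PA), and
the cohort statistics used to quantify after-effects: baseline-relative
response ratios, Grubbs outlier screening, a Shapiro–Wilk log-transform
policy, one-way repeated-measures ANOVA with Dunnett many-to-one
comparisons against baseline, and a predictor × response regression grid.

Because raw recordings for this class of study are rarely shared, the
package includes a synthetic TMS-EMG generator with full ground-truth
annotation, so every detection and statistical stage is testable.

## Who it is for

Researchers analysing single-pulse TMS-EMG protocols (2 kHz surface EMG of
an intrinsic hand muscle, stimulus-locked trials, BL/T10/T20/T40
timepoints) who want reproducible, scriptable versions of the standard
windowed threshold criteria:

* **MEP onset**: rectified EMG > background mean + 3 SD sustained 1 ms
  (25 µV floor at rest); amplitude peak-to-peak over 50 ms.
* **iSP onset**: first ≥ 5 ms run (10 consecutive samples at 2 kHz) with
  rectified EMG at or below 75% of the mean pre-stimulus background
  (a decline ≥ 25%); **offset**: first sustained (> 5 ms) recovery above
  that level. LTI = onset, DTI = offset − onset.
* **cSP**: from the MEP onset to the sustained return of at least 50% of
  the mean pre-stimulus background.

## Worked example

```r
library(tmsemg)

# one synthetic max-contraction trial: 200 uV tonic background, a silent
# period over [32, 61) ms post-stimulus at depth 0.2, noise SD 20 uV
g  <- generate_trace(trace_spec(background_level = 200, noise_sd = 20,
                                sp_onset_ms = 32, sp_offset_ms = 61,
                                sp_depth = 0.2, seed = 42))
bg <- background_stats(g$trace)           # pre-stimulus window [-105, -5) ms
isp <- detect_isp(g$trace, bg)
```

which prints (via `sprintf`):

```
background: 198.4 uV (SD 19.7)
iSP onset 32.0 ms, offset 61.0 ms -> LTI 32.0 ms, DTI 29.0 ms
```

i.e. the detector recovered the constructed suppression window exactly:
the rectified signal stayed below 75% of the 198.4 µV background for a
sustained run starting 32.0 ms post-stimulus and recovered at 61.0 ms.

Cohort level — generate 20 participants with the default stated world
(5% LTI reduction and 10% DTI prolongation post-intervention, MEP response
ratio = 1.5 − 0.2 × AP−LM difference + noise) and analyse:

```r
co  <- generate_cohort(cohort_spec(n_participants = 20, seed = 1))
res <- analyze_cohort(co$records)
res$anova$lti
#> One-way repeated-measures ANOVA: F(2,38) = 16.6, p = 6.594e-06
res$dunnett$lti
#>   timepoint      diff         t   p_adjusted significant
#> 1       t20 -1.601480 -5.074664 2.078203e-05        TRUE
#> 2       t40 -1.546451 -4.900291 3.577444e-05        TRUE
subset(res$table1, response == "mep",
       select = c(predictor, slope, r_squared, p, n))
#>    predictor     slope r_squared        p  n
#> 1     bl_mep -0.000145    0.0553 0.318179 20
#> 5   ap_lm_ld -0.174917    0.4681 0.000878 20
#> 9   pa_lm_ld  0.075184    0.0248 0.507643 20
#> 13  ap_pa_ld -0.148079    0.4450 0.001314 20
```

The LTI reduction injected by the generator is detected (significant at
both post timepoints after Dunnett adjustment), and the regression grid
recovers the AP−LM latency difference as the strongest MEP-response
predictor (r² = 0.47 here; the true slope is −0.2).

## Command-line pipeline

```sh
Rscript -e 'tmsemg::tmsemg_cli(commandArgs(TRUE))' simulate --out run1 --seed 7
Rscript -e 'tmsemg::tmsemg_cli(commandArgs(TRUE))' detect   --in run1 --out run1
Rscript -e 'tmsemg::tmsemg_cli(commandArgs(TRUE))' analyze  --in run1 --out run1
Rscript -e 'tmsemg::tmsemg_cli(commandArgs(TRUE))' report   --in run1 --out run1
```

(equivalently via the installed `exec/tmsemg` script). Trials are stored
as `time_ms,emg_uV` CSVs with JSON metadata sidecars; outputs
(`detection_report.csv`, `records.csv`, `ratios.csv`, `anova.csv`,
`dunnett.csv`, `table1.csv`, `summary.txt`) are stamped with package
version, seed and config hash. Exit codes: 0 success, 2 config error,
3 data error. A JSON config file (`--config`) can override trial counts,
detection parameters, the background window and α; unknown keys are
rejected.

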