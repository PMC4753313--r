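Package: tmsemg
Title: Detection and Cohort Statistics for TMS-Evoked EMG Responses
Version: 0.1.0
Authors@R: person("tmsemg", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing transcranial magnetic stimulation (TMS)
    evoked surface electromyography (EMG): automated detection of motor
    evoked potential (MEP) onset latency and amplitude, of the
    contralateral silent period (cSP) and of the ipsilateral silent period
    (iSP) using windowed threshold criteria on rectified EMG; derivation
    of transcallosal-inhibition indices (latency and duration, LTI/DTI)
    and of coil-orientation latency-difference predictors (AP-LM, PA-LM,
    AP-PA); and the cohort-level statistical pipeline used in
    tDCS after-effect studies (baseline-relative response ratios, Grubbs
    outlier screening, Shapiro-Wilk log-transform policy, one-way
    repeated-measures ANOVA with Dunnett many-to-one post-hoc comparisons
    against baseline, and predictor regressions). A synthetic TMS-EMG
    generator with full ground-truth annotation supports testing every
    stage without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
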