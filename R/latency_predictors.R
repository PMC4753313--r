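# Per-participant mean MEP onset latencies by coil orientation, and the
# latency-difference predictors AP-LM, PA-LM and AP-PA. Small latency
# differences index how easily early I-waves (PA-LM) or late I-waves
# (AP-LM) are recruited relative to direct-wave (LM) activation.

#' Per-participant orientation latencies from a detection report
#'
#' Averages detected MEP onset latencies per participant and coil
#' orientation over active-contraction orientation trials; trials with an
#' undetected onset are dropped from the mean and counted.
#'
#' @param report Detection-report data.frame from [detect_trials()],
#'   filtered (or filterable) to orientation trials: rows with
#'   `coil_orientation` in PA/LM/AP, `task == "light_contraction"` and
#'   `timepoint == "BL"`.
#' @return A data.frame with one row per participant: `pa_ms`, `lm_ms`,
#'   `ap_ms`, `n_pa`, `n_lm`, `n_ap`, `n_undetected`.
#' @export
orientation_latencies <- function(report) {
  stopifnot(is.data.frame(report))
  keep <- report$coil_orientation %in% c("PA", "LM", "AP") &
    report$task == "light_contraction" & report$timepoint == "BL" &
    !is.na(report$mep_detected)
  report <- report[keep, , drop = FALSE]
  if (nrow(report) == 0) stop("no orientation trials in report",
                              call. = FALSE)
  out <- do.call(rbind, lapply(split(report, report$participant_id),
                               function(g) {
    row <- data.frame(participant_id = g$participant_id[1],
                      pa_ms = NA_real_, lm_ms = NA_real_, ap_ms = NA_real_,
                      n_pa = 0L, n_lm = 0L, n_ap = 0L,
                      n_undetected = sum(!g$mep_detected),
                      stringsAsFactors = FALSE)
    for (ori in c("pa", "lm", "ap")) {
      sub <- g[g$coil_orientation == toupper(ori) & g$mep_detected, ,
               drop = FALSE]
      row[[paste0(ori, "_ms")]] <- if (nrow(sub)) mean(sub$mep_onset_ms)
                                   else NA_real_
      row[[paste0("n_", ori)]] <- nrow(sub)
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Coil-orientation latency differences
#'
#' AP-LM and PA-LM differences estimate the relative ease of recruiting
#' late and early I-waves; AP-PA is their difference by construction
#' (`ap_pa = ap_lm - pa_lm`).
#'
#' @param latencies Either a data.frame with columns `pa_ms`, `lm_ms`,
#'   `ap_ms` (e.g. from [orientation_latencies()]) or a single latency
#'   triple given via `pa_ms`, `lm_ms`, `ap_ms`.
#' @param pa_ms,lm_ms,ap_ms Scalar mean latencies in ms (used when
#'   `latencies` is missing).
#' @return The input data.frame with `ap_lm_ms`, `pa_lm_ms`, `ap_pa_ms`
#'   columns added (or a one-row data.frame for scalar input).
#' @export
latency_differences <- function(latencies = NULL, pa_ms = NULL,
                                lm_ms = NULL, ap_ms = NULL) {
  if (is.null(latencies)) {
    latencies <- data.frame(pa_ms = pa_ms %||% NA_real_,
                            lm_ms = lm_ms %||% NA_real_,
                            ap_ms = ap_ms %||% NA_real_)
  }
  stopifnot(is.data.frame(latencies))
  for (col in c("pa_ms", "lm_ms", "ap_ms")) {
    if (is.null(latencies[[col]])) {
      stop(sprintf("missing orientation latency column '%s'", col),
           call. = FALSE)
    }
    if (any(is.na(latencies[[col]]))) {
      stop(sprintf("missing %s latency for participant(s): %s", col,
                   paste(which(is.na(latencies[[col]])), collapse = ", ")),
           call. = FALSE)
    }
  }
  latencies$ap_lm_ms <- latencies$ap_ms - latencies$lm_ms
  latencies$pa_lm_ms <- latencies$pa_ms - latencies$lm_ms
  latencies$ap_pa_ms <- latencies$ap_ms - latencies$pa_ms
  latencies
}
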