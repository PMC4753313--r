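# Cohort-level statistics: baseline-relative response ratios, Grubbs
# outlier screening, Shapiro-Wilk/log-transform policy, classical one-way
# repeated-measures ANOVA, Dunnett many-to-one comparisons against
# baseline, and the predictor-response regression grid.

#' Baseline-relative response ratio
#'
#' Post-intervention values are averaged into a grand mean and expressed
#' relative to baseline; a ratio above 1 indicates facilitation (or
#' lengthening, for durations).
#'
#' @param bl Baseline value (> 0).
#' @param post Numeric vector of post-intervention values (length >= 1).
#' @return `mean(post) / bl`.
#' @export
response_ratio <- function(bl, post) {
  check_number(bl, "bl", lower = .Machine$double.eps)
  if (!is.numeric(post) || length(post) < 1 || any(is.na(post))) {
    stop_field("post", "must be a non-empty numeric vector")
  }
  mean(post) / bl
}

#' Per-participant response ratios for all measures
#'
#' @param records Cohort data.frame with columns `mep_bl/t10/t20`,
#'   `csp_bl/t20/t40`, `lti_bl/t20/t40`, `dti_bl/t20/t40` (e.g. from
#'   [generate_cohort()]).
#' @return A data.frame with `participant_id` and `mep_ratio`,
#'   `csp_ratio`, `lti_ratio`, `dti_ratio`.
#' @export
response_ratios <- function(records) {
  stopifnot(is.data.frame(records))
  posts <- list(mep = c("mep_t10", "mep_t20"),
                csp = c("csp_t20", "csp_t40"),
                lti = c("lti_t20", "lti_t40"),
                dti = c("dti_t20", "dti_t40"))
  out <- data.frame(participant_id = records$participant_id,
                    stringsAsFactors = FALSE)
  for (nm in names(posts)) {
    bl <- records[[paste0(nm, "_bl")]]
    post <- as.matrix(records[, posts[[nm]], drop = FALSE])
    out[[paste0(nm, "_ratio")]] <- rowMeans(post) / bl
  }
  out
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs statistic `Z = max |x - mean| / SD` compared against
#' the t-distribution critical value
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n-2)`. At most one value is flagged per call.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param alpha Significance level (default 0.05).
#' @return A list with `statistic` (Z), `critical`, `p_value`,
#'   `outlier_index` (`NA` if none flagged) and `flagged`.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  if (!is.numeric(values) || length(values) < 3) {
    stop_field("values", "Grubbs test needs at least 3 values")
  }
  n <- length(values)
  s <- sd(values)
  if (s == 0) {
    return(list(statistic = 0, critical = NA_real_, p_value = 1,
                outlier_index = NA_integer_, flagged = FALSE))
  }
  dev <- abs(values - mean(values))
  z <- max(dev) / s
  tcrit <- qt(1 - alpha / (2 * n), df = n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  # invert Z back to a t statistic for an approximate p-value
  denom <- (n - 1)^2 - n * z^2
  p <- if (denom <= 0) 0 else {
    ts <- sqrt((n - 2) * n * z^2 / denom)
    min(1, 2 * n * pt(ts, df = n - 2, lower.tail = FALSE))
  }
  flagged <- z > crit
  list(statistic = z, critical = crit, p_value = p,
       outlier_index = if (flagged) which.max(dev) else NA_integer_,
       flagged = flagged)
}

#' Shapiro-Wilk screening with log-transform policy
#'
#' Applies the Shapiro-Wilk test and natural-log transforms the values iff
#' normality is rejected at `alpha` (the policy used for MEP amplitudes,
#' which are typically right-skewed).
#'
#' @param values Numeric vector (3 <= n <= 5000, not all equal).
#' @param alpha Rejection level for the Shapiro-Wilk test (default 0.05).
#' @return A list with `values` (possibly transformed), `transformed`
#'   (flag) and `shapiro_p`.
#' @export
check_normality_and_transform <- function(values, alpha = 0.05) {
  if (!is.numeric(values) || length(values) < 3) {
    stop_field("values", "need at least 3 values")
  }
  if (sd(values) == 0) {
    stop_field("values",
               "Shapiro-Wilk is undefined for identical values")
  }
  p <- shapiro.test(values)$p.value
  if (p < alpha) {
    if (any(values <= 0)) {
      stop_field("values",
                 "log-transform required but values are not all positive")
    }
    list(values = log(values), transformed = TRUE, shapiro_p = p)
  } else {
    list(values = values, transformed = FALSE, shapiro_p = p)
  }
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject sums of squares on an `n participants x k
#' timepoints` matrix: `F = MS_time / MS_error` with degrees of freedom
#' `(k - 1, (k - 1)(n - 1))`. Participants with missing cells are dropped
#' (listwise) with a message.
#'
#' @param mat Numeric matrix, participants in rows, timepoints in columns
#'   (first column conventionally baseline).
#' @return A list of class `rm_anova` with `F`, `df_effect`, `df_error`,
#'   `p`, `ms_error`, `n`, `k`, per-timepoint `means` and `sds`, and
#'   `n_dropped`.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat) || ncol(mat) < 2) {
    stop_field("mat", "need a numeric matrix with >= 2 timepoints")
  }
  cc <- complete.cases(mat)
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    message(sprintf("rm_anova: dropped %d participant(s) with missing cells",
                    n_dropped))
  }
  mat <- mat[cc, , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2) stop_field("mat", "need >= 2 complete participants")
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ss_time <- n * sum((col_m - grand)^2)
  resid <- mat - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_err <- ss_err / df2
  f <- if (ms_err == 0) {
    if (ss_time == 0) 0 else Inf
  } else (ss_time / df1) / ms_err
  p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
  if (f == 0 && ms_err == 0) p <- 1
  structure(list(F = f, df_effect = df1, df_error = df2, p = p,
                 ms_error = ms_err, n = n, k = k,
                 means = col_m, sds = apply(mat, 2, sd),
                 n_dropped = n_dropped),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("One-way repeated-measures ANOVA: F(%d,%d) = %.3g, p = %.4g\n",
              x$df_effect, x$df_error, x$F, x$p))
  invisible(x)
}

# P(max_j |T_j| <= q) for m correlation-1/2 equicorrelated t variables on
# `df` degrees of freedom (the two-sided many-to-one Dunnett
# distribution), by nested quadrature over the shared scale factor and the
# common normal factor.
dunnett_pmax <- function(q, m, df) {
  if (q <= 0) return(0)
  inner <- function(a) {
    # P(all |u_j - u_0| <= a), u iid standard normal
    integrate(function(u) dnorm(u) * (pnorm(u + a) - pnorm(u - a))^m,
              -Inf, Inf, rel.tol = 1e-10)$value
  }
  g <- function(s) {
    # density of sqrt(chi^2_df / df)
    exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
          (df - 1) * log(s) - df * s^2 / 2)
  }
  integrate(function(s) {
    vapply(s, function(si) g(si) * inner(q * si * sqrt(2)), 0)
  }, 0, Inf, rel.tol = 1e-8)$value
}

# Monte-Carlo version of dunnett_pmax (independent fallback / oracle).
dunnett_pmax_mc <- function(q, m, df, nsim = 1e5, seed = NULL) {
  with_seed(seed, {
    u0 <- rnorm(nsim)
    s <- sqrt(rchisq(nsim, df) / df)
    mx <- rep(0, nsim)
    for (j in seq_len(m)) {
      mx <- pmax(mx, abs(rnorm(nsim) - u0) / sqrt(2))
    }
    mean(mx / s <= q)
  })
}

#' Dunnett critical value (many-to-one, two-sided)
#'
#' @param alpha Familywise level.
#' @param m Number of comparisons against the control.
#' @param df Error degrees of freedom.
#' @return The two-sided critical value `q` with
#'   `P(max |T_j| <= q) = 1 - alpha`.
#' @export
dunnett_critical <- function(alpha, m, df) {
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  uniroot(function(q) dunnett_pmax(q, m, df) - (1 - alpha),
          lower = 1e-6, upper = 50, tol = 1e-8)$root
}

#' Dunnett many-to-one comparisons against baseline
#'
#' After a repeated-measures ANOVA, compares each post timepoint with the
#' control (baseline) column: `t_i = (mean_i - mean_BL) /
#' sqrt(2 * MS_error / n)`, with two-sided p-values adjusted under the
#' correlation-1/2 multivariate-t many-to-one distribution on the ANOVA
#' error degrees of freedom.
#'
#' @param mat The matrix passed to [rm_anova()].
#' @param control Index of the control (baseline) column, default 1.
#' @param alpha Familywise significance level (default 0.05).
#' @param anova Optional precomputed [rm_anova()] result for `mat`.
#' @return A data.frame of class `dunnett_result`, one row per comparison:
#'   `timepoint`, `diff`, `t`, `p_adjusted`, `significant`; the critical
#'   value and `ms_error` are attached as attributes. If `MS_error` is 0
#'   the comparisons degenerate to exact equality checks (`t` is `NA`, `p`
#'   is 0 or 1).
#' @export
dunnett_vs_baseline <- function(mat, control = 1, alpha = 0.05,
                                anova = NULL) {
  mat <- as.matrix(mat)
  mat <- mat[complete.cases(mat), , drop = FALSE]
  if (is.null(anova)) anova <- rm_anova(mat)
  k <- ncol(mat); n <- nrow(mat)
  idx <- setdiff(seq_len(k), control)
  m <- length(idx)
  labs <- colnames(mat) %||% paste0("col", seq_len(k))
  diffs <- colMeans(mat)[idx] - mean(mat[, control])
  if (anova$ms_error == 0) {
    out <- data.frame(timepoint = labs[idx], diff = diffs, t = NA_real_,
                      p_adjusted = ifelse(diffs == 0, 1, 0),
                      significant = diffs != 0, stringsAsFactors = FALSE)
    attr(out, "critical") <- NA_real_
  } else {
    se <- sqrt(2 * anova$ms_error / n)
    tstat <- diffs / se
    padj <- vapply(abs(tstat), function(tt) {
      if (tt == 0) return(1)
      min(1, 1 - dunnett_pmax(tt, m, anova$df_error))
    }, 0)
    crit <- dunnett_critical(alpha, m, anova$df_error)
    out <- data.frame(timepoint = labs[idx], diff = diffs, t = tstat,
                      p_adjusted = padj, significant = padj < alpha,
                      stringsAsFactors = FALSE)
    attr(out, "critical") <- crit
  }
  attr(out, "ms_error") <- anova$ms_error
  attr(out, "df_error") <- anova$df_error
  class(out) <- c("dunnett_result", "data.frame")
  rownames(out) <- NULL
  out
}

#' Predictor-response regression grid
#'
#' Ordinary least-squares regressions of every response ratio on every
#' predictor: baseline MEP amplitude and the AP-LM, PA-LM, AP-PA latency
#' differences against the MEP, cSP, LTI and DTI response ratios (a 4 x 4
#' grid).
#'
#' @param records Cohort data.frame with latency-difference columns
#'   (`ap_lm_ms`, `pa_lm_ms`, `ap_pa_ms`) and `mep_bl`.
#' @param ratios Optional precomputed [response_ratios()] table; computed
#'   from `records` when absent.
#' @param exclude_mep_ids Participant ids excluded from regressions whose
#'   response is the MEP ratio (outlier policy).
#' @return A data.frame with one row per predictor-response pair:
#'   `predictor`, `response`, `slope`, `intercept`, `r_squared`, `p`, `n`,
#'   `flagged` (TRUE when the predictor has zero variance).
#' @export
regress_predictors <- function(records, ratios = NULL,
                               exclude_mep_ids = character(0)) {
  if (is.null(ratios)) ratios <- response_ratios(records)
  predictors <- list(bl_mep = records$mep_bl,
                     ap_lm_ld = records$ap_lm_ms,
                     pa_lm_ld = records$pa_lm_ms,
                     ap_pa_ld = records$ap_pa_ms)
  responses <- list(mep = ratios$mep_ratio, csp = ratios$csp_ratio,
                    lti = ratios$lti_ratio, dti = ratios$dti_ratio)
  rows <- list()
  for (pn in names(predictors)) {
    for (rn in names(responses)) {
      x <- predictors[[pn]]; y <- responses[[rn]]
      if (rn == "mep" && length(exclude_mep_ids)) {
        keep <- !(records$participant_id %in% exclude_mep_ids)
        x <- x[keep]; y <- y[keep]
      }
      ok <- is.finite(x) & is.finite(y)
      x <- x[ok]; y <- y[ok]
      if (length(x) < 3) {
        stop(sprintf("regression %s ~ %s needs >= 3 complete pairs", rn,
                     pn), call. = FALSE)
      }
      if (sd(x) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          predictor = pn, response = rn, slope = NA_real_,
          intercept = NA_real_, r_squared = NA_real_, p = NA_real_,
          n = length(x), flagged = TRUE, stringsAsFactors = FALSE)
        next
      }
      fit <- lm(y ~ x)
      # noiseless cohorts legitimately produce perfect fits; summary()
      # warns about them
      sm <- suppressWarnings(summary(fit))
      pval <- if (sd(y) == 0) 1 else sm$coefficients["x", "Pr(>|t|)"]
      rows[[length(rows) + 1]] <- data.frame(
        predictor = pn, response = rn,
        slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
        r_squared = if (sd(y) == 0) 0 else sm$r.squared,
        p = pval, n = length(x), flagged = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

measure_matrix <- function(records, measure) {
  cols <- switch(measure,
                 mep = c("mep_bl", "mep_t10", "mep_t20"),
                 csp = c("csp_bl", "csp_t20", "csp_t40"),
                 lti = c("lti_bl", "lti_t20", "lti_t40"),
                 dti = c("dti_bl", "dti_t20", "dti_t40"),
                 stop("unknown measure: ", measure, call. = FALSE))
  m <- as.matrix(records[, cols, drop = FALSE])
  colnames(m) <- sub(".*_", "", cols)
  rownames(m) <- records$participant_id
  m
}

#' Full cohort analysis
#'
#' Runs the whole statistical pipeline on a cohort table: response ratios;
#' Grubbs screening of the MEP ratios (a flagged participant is excluded
#' from the MEP analyses only); per measure, the Shapiro-Wilk
#' log-transform policy, repeated-measures ANOVA and Dunnett comparisons
#' against baseline; and the predictor-response regression grid.
#'
#' @param records Cohort data.frame (one row per participant; see
#'   [generate_cohort()]).
#' @param alpha Significance level used throughout (default 0.05).
#' @return A list with `ratios`, `grubbs`, `excluded_mep_ids`, `anova`
#'   (per measure: the [rm_anova()] result plus `transformed` flag),
#'   `dunnett` (per measure) and `table1` (the regression grid).
#' @export
analyze_cohort <- function(records, alpha = 0.05) {
  ratios <- response_ratios(records)
  gr <- grubbs_test(ratios$mep_ratio, alpha = alpha)
  excluded <- if (gr$flagged)
    ratios$participant_id[gr$outlier_index] else character(0)
  anovas <- list(); dunnetts <- list()
  for (measure in c("mep", "csp", "lti", "dti")) {
    recs <- records
    if (measure == "mep" && length(excluded)) {
      recs <- records[!(records$participant_id %in% excluded), ,
                      drop = FALSE]
    }
    m <- measure_matrix(recs, measure)
    m <- m[complete.cases(m), , drop = FALSE]
    nt <- tryCatch(check_normality_and_transform(as.vector(m), alpha),
                   error = function(e) list(values = as.vector(m),
                                            transformed = FALSE,
                                            shapiro_p = NA_real_))
    mm <- if (nt$transformed) log(m) else m
    an <- rm_anova(mm)
    an$transformed <- nt$transformed
    an$shapiro_p <- nt$shapiro_p
    anovas[[measure]] <- an
    dunnetts[[measure]] <- dunnett_vs_baseline(mm, alpha = alpha,
                                               anova = an)
  }
  list(ratios = ratios, grubbs = gr, excluded_mep_ids = excluded,
       anova = anovas, dunnett = dunnetts,
       table1 = regress_predictors(records, ratios,
                                   exclude_mep_ids = excluded),
       alpha = alpha)
}
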