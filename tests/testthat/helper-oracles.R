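# Independent oracles, coded by brute force and kept free of the package's
# internal run/threshold machinery.

# Exhaustive window scan: first 1-based index i in [from, to] such that
# cmp holds for every one of the next run_len samples.
oracle_first_run <- function(x, thr, run_len, from, to,
                             cmp = c("le", "gt", "ge")) {
  cmp <- match.arg(cmp)
  for (i in from:min(to, length(x) - run_len + 1)) {
    seg <- x[i:(i + run_len - 1)]
    ok <- switch(cmp,
                 le = all(seg <= thr),
                 gt = all(seg > thr),
                 ge = all(seg >= thr))
    if (ok) return(i)
  }
  NA_integer_
}

# iSP onset/offset straight from the documented rule, as 1-based sample
# indices: decline = run of >= run_on samples of |x| at or below
# (1 - f) * bg; recovery = subsequent run of >= run_off samples above it.
oracle_isp_indices <- function(samples, stim_idx0, rate, bg_mean,
                               decline_fraction = 0.25, run_on_ms = 5,
                               run_off_ms = 5, blank_ms = 5,
                               search_end_ms = 150) {
  r <- abs(samples)
  thr <- (1 - decline_fraction) * bg_mean
  to_idx <- function(ms) round(ms * rate / 1000) + stim_idx0 + 1
  run_on <- round(run_on_ms * rate / 1000)
  run_off <- round(run_off_ms * rate / 1000)
  on <- oracle_first_run(r, thr, run_on, to_idx(blank_ms),
                         to_idx(search_end_ms), "le")
  if (is.na(on)) return(list(onset = NA, offset = NA))
  off <- oracle_first_run(r, thr, run_off, on + 1, to_idx(search_end_ms),
                          "gt")
  list(onset = on, offset = off)
}

# Repeated-measures ANOVA by explicit elementwise loops over the
# within-subject decomposition.
oracle_rm_anova <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_time <- 0
  for (j in 1:k) ss_time <- ss_time + n * (mean(mat[, j]) - grand)^2
  ss_err <- 0
  for (i in 1:n) {
    for (j in 1:k) {
      ss_err <- ss_err +
        (mat[i, j] - mean(mat[i, ]) - mean(mat[, j]) + grand)^2
    }
  }
  f <- (ss_time / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(F = f, df1 = k - 1, df2 = (k - 1) * (n - 1),
       p = pf(f, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
}

# Grubbs statistic and two-sided critical value, written out from the
# t-distribution formula.
oracle_grubbs <- function(x, alpha = 0.05) {
  n <- length(x)
  g <- max(abs(x - mean(x))) / sd(x)
  tval <- qt(1 - alpha / (2 * n), n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tval^2 / (n - 2 + tval^2))
  list(statistic = g, critical = crit, flagged = g > crit,
       index = which.max(abs(x - mean(x))))
}

# Monte-Carlo draw of max_j |T_j| for the many-to-one Dunnett family with
# correlation 1/2 on df error degrees of freedom.
oracle_dunnett_maxt <- function(m, df, nsim, seed) {
  set.seed(seed)
  u0 <- rnorm(nsim)
  s <- sqrt(rchisq(nsim, df) / df)
  mx <- rep(0, nsim)
  for (j in 1:m) mx <- pmax(mx, abs(rnorm(nsim) - u0) / sqrt(2))
  mx / s
}

# Shared fixture: a null cohort spec (no intervention effect anywhere, no
# predictor effect).
null_cohort_spec <- function(seed, n = 20) {
  cohort_spec(
    n_participants = n, true_slope = 0, true_intercept = 1,
    measures = cohort_measures(
      csp = list(bl_mean = 120, bl_sd = 25, effects = c(T20 = 1, T40 = 1),
                 measurement_cv = 0.05),
      lti = list(bl_mean = 35, bl_sd = 4, effects = c(T20 = 1, T40 = 1),
                 measurement_cv = 0.03),
      dti = list(bl_mean = 25, bl_sd = 6, effects = c(T20 = 1, T40 = 1),
                 measurement_cv = 0.06)),
    seed = seed)
}

lti_matrix <- function(cohort) {
  as.matrix(cohort$records[, c("lti_bl", "lti_t20", "lti_t40")])
}
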