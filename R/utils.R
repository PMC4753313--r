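# Internal helpers shared across modules.

#' @importFrom stats rnorm runif sd qt pt pf dnorm pnorm integrate uniroot
#'   shapiro.test lm coef rchisq complete.cases setNames
NULL

# Evaluate `expr` under a private RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("%s: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (allow_na && (is.null(x) || length(x) == 0 || all(is.na(x)))) {
    return(invisible(NULL))
  }
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (x < lower || x > upper) {
    stop_field(field, sprintf("must be in [%s, %s], got %s", lower, upper, x))
  }
  invisible(NULL)
}

# Causal running mean over a window of `w` samples: y[i] = mean(x[i:(i+w-1)]),
# defined for i in 1:(n-w+1); the trailing w-1 positions are filled with the
# last full-window value so downstream run logic sees a complete vector.
running_mean <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n < w) return(x)
  cs <- cumsum(c(0, x))
  y <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  c(y, rep(y[length(y)], w - 1))
}

# First index i in [from, to] such that cmp(x[i..i+run_len-1]) holds for every
# sample (run must fit inside the vector). Returns NA_integer_ if none.
first_sustained_run <- function(ok, run_len, from, to) {
  n <- length(ok)
  from <- max(1L, as.integer(from))
  to <- min(as.integer(to), n - run_len + 1L)
  if (from > to) return(NA_integer_)
  r <- rle(ok[from:(min(to + run_len - 1L, n))])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= run_len & starts <= (to - from + 1L))
  # a long run may begin before `from` was reached; starts are already
  # relative to `from`, so any qualifying run is valid
  if (length(hit) == 0) return(NA_integer_)
  as.integer(from + starts[hit[1]] - 1L)
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used to stamp
# output files with a configuration fingerprint without extra dependencies.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; keep h in doubles (fits 2^32)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, split into
    # 16-bit halves so intermediates stay exactly representable
    hi <- floor(h / 65536)
    h <- (((hi * 16777619) %% 65536) * 65536 +
            (h %% 65536) * 16777619) %% 4294967296
  }
  # render as hex from the two 16-bit halves (h is a double)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
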