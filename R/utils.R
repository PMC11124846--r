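# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  trunc(abs(x) * m + 0.5) / m * sign(x)
}

# Centered running mean with shrink-to-available edges, via cumulative sums.
# k must be odd; window at index i is [i - h, i + h] clipped to [1, n].
running_mean_centered <- function(x, k) {
  stopifnot(k >= 1, k %% 2 == 1)
  n <- length(x)
  h <- (k - 1L) / 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Rolling min/max over a trailing window of w elements (positions w..n).
roll_extreme <- function(x, w, fun = pmin) {
  n <- length(x)
  if (w > n) return(numeric(0))
  if (w == 1L) return(x)
  do.call(fun, lapply(seq_len(w), function(j) x[j:(n - w + j)]))
}

# Derive a child seed from a base seed and an index; stays within 32-bit range.
child_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 1000003) * 2011 + as.numeric(i) * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
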