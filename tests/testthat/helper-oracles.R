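# Independent brute-force oracles used to cross-check the package's
# implementations.  These deliberately re-derive each quantity with plain
# loops / enumeration, sharing no code with the package internals.

# interior strict local maxima with prominence filtering, loop version
oracle_peaks <- function(doy, values, prominence_frac) {
  n <- length(values)
  out_doy <- numeric(0); out_h <- numeric(0)
  thr <- prominence_frac * max(values)
  for (i in 2:(n - 1)) {
    if (!(values[i] > values[i - 1] && values[i] > values[i + 1])) next
    # walk left to the nearest higher point, tracking the lowest saddle
    lo_l <- Inf
    j <- i - 1
    while (j >= 1 && values[j] <= values[i]) { lo_l <- min(lo_l, values[j]); j <- j - 1 }
    lo_r <- Inf
    j <- i + 1
    while (j <= n && values[j] <= values[i]) { lo_r <- min(lo_r, values[j]); j <- j + 1 }
    if (values[i] - max(lo_l, lo_r) >= thr) {
      out_doy <- c(out_doy, doy[i]); out_h <- c(out_h, values[i])
    }
  }
  data.frame(doy = out_doy, height = out_h)
}

# asymmetric check loss of a candidate quantile line
oracle_check_loss <- function(year, doy, a, b, tau) {
  r <- doy - a - b * year
  sum(ifelse(r >= 0, tau * r, (tau - 1) * r))
}

# exact least-absolute-deviations line by all-pairs vertex enumeration
oracle_lad_loss <- function(x, y) {
  n <- length(x)
  best <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[i] == x[j]) next
    b <- (y[j] - y[i]) / (x[j] - x[i])
    a <- y[i] - b * x[i]
    best <- min(best, sum(abs(y - a - b * x)))
  }
  best
}

# random wiggly test curve on a 1-day grid
random_curve <- function(n, seed) {
  set.seed(seed)
  x <- seq_len(n)
  v <- as.numeric(stats::filter(rnorm(n), rep(1 / 7, 7), sides = 2,
                                circular = TRUE))
  v - min(v) + 0.05
}
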