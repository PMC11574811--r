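# Independent brute-force oracles and small fixture builders.

# Build a psd_estimate directly from a log10-power sequence.
make_psd <- function(log_power, freqs = seq_along(log_power)) {
  structure(list(freqs = freqs, power = 10^log_power, log_power = log_power,
                 fs = NA_real_, window_s = NA_real_, n_segments = NA_integer_,
                 band = range(freqs)),
            class = "psd_estimate")
}

# Literal walk of the prominence definition: trace a horizontal line from
# the peak left and right until the signal end or a sample above the peak;
# take the minimum of each traced segment; prominence is peak height minus
# the greater minimum.
oracle_prominence <- function(values, i) {
  h <- values[i]
  n <- length(values)
  lstop <- 0L
  for (j in (i - 1L):1L) if (values[j] > h) { lstop <- j; break }
  rstop <- n + 1L
  for (j in (i + 1L):n) if (values[j] > h) { rstop <- j; break }
  left_seg <- values[(lstop + 1L):(i - 1L)]
  right_seg <- values[(i + 1L):(rstop - 1L)]
  h - max(min(left_seg), min(right_seg))
}

# Literal half-prominence width: reference line at height - prominence/2,
# first crossing of each descending slope, linear interpolation.
oracle_width <- function(values, grid, i, prom) {
  ref <- values[i] - prom / 2
  h <- values[i]
  n <- length(values)
  left <- grid[1L]
  for (j in (i - 1L):1L) {
    if (values[j] > h) break
    if (values[j] <= ref) {
      left <- grid[j] + (grid[j + 1L] - grid[j]) *
        (ref - values[j]) / (values[j + 1L] - values[j])
      break
    }
  }
  right <- grid[n]
  for (j in (i + 1L):n) {
    if (values[j] > h) break
    if (values[j] <= ref) {
      right <- grid[j - 1L] + (grid[j] - grid[j - 1L]) *
        (values[j - 1L] - ref) / (values[j - 1L] - values[j])
      break
    }
  }
  right - left
}

# Direct O(n * lags) biased autocorrelation of the mean-removed series.
oracle_acf <- function(x, max_lag) {
  x <- x - mean(x)
  n <- length(x)
  denom <- sum(x^2)
  vapply(0:max_lag, function(k)
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / denom, 0)
}

# Build an acf_result by hand for threshold-scan tests.
make_acf <- function(values, fs) {
  structure(list(lags = (seq_along(values) - 1L) / fs, values = values,
                 fs = fs), class = "acf_result")
}

# Random piecewise-smooth sequences on which peak oracles are exercised.
random_sequence <- function(n) {
  cumsum(stats::rnorm(n)) + stats::rnorm(n, sd = 0.3)
}
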