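#' Welch power spectral density estimate
#'
#' Splits the series into `window_s`-second segments with fractional
#' `overlap`, linearly detrends each segment, applies a Hamming taper,
#' and averages the one-sided modified periodograms. Density (per-Hz)
#' normalization is used, so integrating the power over frequency
#' approximates the series variance.
#'
#' @param series numeric time series.
#' @param fs sampling rate in Hz.
#' @param window_s segment length in seconds (default 3, giving a frequency
#'   grid spacing of 1/3 Hz).
#' @param overlap fractional overlap between consecutive segments in
#'   `[0, 1)`; default 0.5.
#' @param detrend linearly detrend each segment before tapering (default
#'   `TRUE`).
#' @return A `psd_estimate`: list with `freqs` (Hz), `power` (linear
#'   density), `log_power` (log10 of power; zero-power bins map to `-Inf`),
#'   `fs`, `window_s`, `n_segments`.
#' @export
welch_psd <- function(series, fs, window_s = 3, overlap = 0.5,
                      detrend = TRUE) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(window_s, "window_s", positive = TRUE)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must lie in [0, 1)")
  L <- round(window_s * fs)
  n <- length(series)
  if (n < L) stop("insufficient data: series shorter than one window")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1L)) / (L - 1L))  # Hamming
  u <- fs * sum(w^2)                                        # density norm
  t0 <- seq_len(L) - (L + 1) / 2                            # centered time
  stt <- sum(t0^2)
  n_freq <- L %/% 2L + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- series[s:(s + L - 1L)]
    if (detrend) seg <- seg - mean(seg) - (sum(seg * t0) / stt) * t0
    spec <- Mod(stats::fft(seg * w)[seq_len(n_freq)])^2 / u
    acc <- acc + spec
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, n_freq); dbl[1L] <- 1
  if (L %% 2L == 0L) dbl[n_freq] <- 1
  p <- p * dbl
  freqs <- (seq_len(n_freq) - 1L) * fs / L
  new_psd(freqs, p, fs = fs, window_s = window_s, n_segments = length(starts))
}

new_psd <- function(freqs, power, fs, window_s, n_segments, band = NULL) {
  structure(list(freqs = freqs, power = power,
                 log_power = ifelse(power > 0, log10(power), -Inf),
                 fs = fs, window_s = window_s, n_segments = n_segments,
                 band = band),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate: %d bins, %.3g-%.3g Hz (step %.3g Hz), %d segments%s>\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$n_segments %||% NA,
              if (!is.null(x$band)) sprintf(", band %g-%g Hz",
                                            x$band[1], x$band[2]) else ""))
  invisible(x)
}

#' @export
plot.psd_estimate <- function(x, ...) {
  ok <- is.finite(x$log_power)
  graphics::plot(x$freqs[ok], x$log_power[ok], type = "l",
                 xlab = "Frequency (Hz)",
                 ylab = expression(log[10] ~ "power (" * mu * V^2 / Hz * ")"),
                 ...)
  invisible(x)
}

#' Average power spectra across electrodes of a region of interest
#'
#' Pointwise mean of the linear power across spectra sharing one frequency
#' grid; the log10 power is recomputed from the averaged linear power
#' (averaging precedes the log step).
#'
#' @param psds list of `psd_estimate` objects on identical grids.
#' @return The averaged `psd_estimate`.
#' @export
roi_average_psd <- function(psds) {
  if (!length(psds)) stop("empty PSD list")
  f0 <- psds[[1L]]$freqs
  for (p in psds) {
    if (length(p$freqs) != length(f0) || any(abs(p$freqs - f0) > 1e-9)) {
      stop("all PSDs must share one frequency grid")
    }
  }
  pw <- Reduce(`+`, lapply(psds, `[[`, "power")) / length(psds)
  new_psd(f0, pw, fs = psds[[1L]]$fs, window_s = psds[[1L]]$window_s,
          n_segments = psds[[1L]]$n_segments, band = psds[[1L]]$band)
}

#' Restrict a spectrum to the analysis band
#'
#' Keeps the inclusive sub-grid `[low, high]`; all downstream peak and
#' extremum analysis operates on this restriction.
#'
#' @param psd a `psd_estimate`.
#' @param low,high band edges in Hz (defaults 0.5 and 40).
#' @return The restricted `psd_estimate` with its `band` recorded.
#' @export
restrict_band <- function(psd, low = 0.5, high = 40) {
  if (low >= high) stop("`low` must be below `high`")
  keep <- psd$freqs >= low - 1e-9 & psd$freqs <= high + 1e-9
  if (!any(keep)) stop("band restriction leaves no frequency bins")
  new_psd(psd$freqs[keep], psd$power[keep], fs = psd$fs,
          window_s = psd$window_s, n_segments = psd$n_segments,
          band = c(low, high))
}
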