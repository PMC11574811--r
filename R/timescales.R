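#' Autocorrelation function of a time series
#'
#' Biased (1/n) autocorrelation of the mean-removed series, computed via
#' FFT (Wiener-Khinchin), normalized so the lag-0 value is exactly 1. The
#' biased estimator guarantees |values| <= 1 and positive semidefiniteness.
#'
#' @param series numeric time series with positive variance.
#' @param fs sampling rate in Hz.
#' @param max_lag_s largest lag in seconds (< series duration; default 20).
#' @return An `acf_result`: list with `lags` (seconds, starting at 0,
#'   spacing 1/fs), `values` (correlations), `fs`.
#' @export
autocorrelation <- function(series, fs, max_lag_s = 20) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  n <- length(series)
  if (max_lag_s >= n / fs) stop("`max_lag_s` must be below the series duration")
  x <- series - mean(series)
  if (sum(x^2) == 0) stop("degenerate signal: zero variance")
  L <- round(max_lag_s * fs)
  nfft <- stats::nextn(2L * n, 2)
  s <- stats::fft(c(x, rep(0, nfft - n)))
  acov <- Re(stats::fft(Mod(s)^2, inverse = TRUE))[seq_len(L + 1L)] / nfft
  structure(list(lags = (0:L) / fs, values = acov / acov[1L], fs = fs),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("<acf_result: %d lags, 0-%.3g s @ %g Hz>\n",
              length(x$lags), max(x$lags), x$fs))
  invisible(x)
}

#' @export
plot.acf_result <- function(x, ...) {
  graphics::plot(x$lags, x$values, type = "l", xlab = "Lag (s)",
                 ylab = "Autocorrelation", ...)
  graphics::abline(h = c(0.5, exp(-1), 0), lty = 3, col = "grey50")
  invisible(x)
}

#' Autocorrelation window at a threshold
#'
#' First lag at which the autocorrelation reaches (drops to or below) the
#' threshold, in seconds. If the threshold is never reached within the
#' computed lag range, the maximum lag is returned with `censored = TRUE`.
#'
#' @param acf an `acf_result`.
#' @param threshold correlation threshold (< 1), e.g. 0.5, `exp(-1)`, 0.
#' @return List: `seconds`, `censored`.
#' @export
acw <- function(acf, threshold) {
  if (threshold >= 1) stop("`threshold` must be below 1")
  hit <- which(acf$values[-1L] <= threshold)
  if (!length(hit)) {
    list(seconds = max(acf$lags), censored = TRUE)
  } else {
    list(seconds = acf$lags[hit[1L] + 1L], censored = FALSE)
  }
}

#' The three autocorrelation-window statistics of a series
#'
#' ACW-50, ACW-e^-1 and ACW-0: the first lags at which the autocorrelation
#' drops to 0.5, e^-1 and 0, all read off a single autocorrelation
#' evaluation. Since the thresholds decrease, the uncensored values satisfy
#' `acw50 <= acw_e <= acw0`.
#'
#' @inheritParams autocorrelation
#' @return An `acw_triplet`: one-row data frame with `acw50`, `acw_e`,
#'   `acw0` (seconds) and the matching `censored_*` flags.
#' @export
acw_triplet <- function(series, fs, max_lag_s = 20) {
  a <- autocorrelation(series, fs, max_lag_s)
  t50 <- acw(a, 0.5); te <- acw(a, exp(-1)); t0 <- acw(a, 0)
  out <- data.frame(acw50 = t50$seconds, acw_e = te$seconds,
                    acw0 = t0$seconds, censored_acw50 = t50$censored,
                    censored_acw_e = te$censored, censored_acw0 = t0$censored)
  class(out) <- c("acw_triplet", "data.frame")
  out
}

#' Average autocorrelation windows across ROI electrodes
#'
#' Arithmetic mean per measure across channels. Censored members raise a
#' warning and are excluded from the mean; the censored flag propagates.
#'
#' @param triplets list of `acw_triplet` rows (one per channel).
#' @return One averaged `acw_triplet` row.
#' @export
roi_average_acw <- function(triplets) {
  if (!length(triplets)) stop("empty triplet list")
  tab <- do.call(rbind, triplets)
  avg <- function(vals, cens) {
    if (any(cens)) {
      warning("censored autocorrelation window excluded from ROI average")
      if (all(cens)) return(c(NA_real_, TRUE))
    }
    c(mean(vals[!cens]), any(cens))
  }
  a50 <- avg(tab$acw50, tab$censored_acw50)
  ae <- avg(tab$acw_e, tab$censored_acw_e)
  a0 <- avg(tab$acw0, tab$censored_acw0)
  out <- data.frame(acw50 = a50[1L], acw_e = ae[1L], acw0 = a0[1L],
                    censored_acw50 = as.logical(a50[2L]),
                    censored_acw_e = as.logical(ae[2L]),
                    censored_acw0 = as.logical(a0[2L]))
  class(out) <- c("acw_triplet", "data.frame")
  out
}
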