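#' Pre-processing configuration
#'
#' Bundles the parameters of the pre-processing chain: target sampling rate,
#' band-pass edges, bad-channel criteria, clip length and the two regions of
#' interest (ROI).
#'
#' @param target_fs target sampling rate in Hz after downsampling.
#' @param band band-pass edges `c(low, high)` in Hz.
#' @param flatline_s a channel constant for longer than this many seconds is
#'   flagged as flatline.
#' @param corr_thresh absolute between-channel correlation above which the
#'   later-indexed channel of the pair is flagged.
#' @param burst_sd robust-SD multiple beyond which samples count as bursts.
#' @param clip_s final clipped recording length in seconds.
#' @param frontal_labels,occipital_labels ROI electrode labels.
#' @return A `preproc_config` list.
#' @export
preproc_config <- function(target_fs = 250, band = c(0.5, 40),
                           flatline_s = 5, corr_thresh = 0.8, burst_sd = 5,
                           clip_s = 300,
                           frontal_labels = c("Fz", "F1", "F2"),
                           occipital_labels = c("Oz", "O1", "O2")) {
  if (band[1] <= 0 || band[1] >= band[2] || band[2] >= target_fs / 2) {
    stop("band must satisfy 0 < low < high < target_fs/2")
  }
  structure(list(target_fs = target_fs, band = band, flatline_s = flatline_s,
                 corr_thresh = corr_thresh, burst_sd = burst_sd,
                 clip_s = clip_s, frontal_labels = frontal_labels,
                 occipital_labels = occipital_labels),
            class = "preproc_config")
}

# Zero-phase FIR application: linear-phase filter applied by FFT
# convolution with the group delay (ntaps-1)/2 compensated. The signal is
# extended with its edge values so that boundaries do not look like steps.
apply_fir <- function(x, h) {
  n <- length(x)
  nh <- length(h)
  delay <- (nh - 1L) %/% 2L
  xp <- c(rep(x[1L], nh), x, rep(x[n], nh))
  np <- length(xp)
  nfft <- stats::nextn(np + nh - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(xp, rep(0, nfft - np))) *
                     stats::fft(c(h, rep(0, nfft - nh))), inverse = TRUE)) / nfft
  y[(nh + delay + 1L):(nh + delay + n)]
}

#' Downsample a recording to a divisor rate
#'
#' Anti-alias low-pass filtering (zero-phase FIR at 90 % of the new Nyquist)
#' followed by decimation.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs new sampling rate; must divide `rec$fs`.
#' @return The downsampled recording.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot_scalar(target_fs, "target_fs", positive = TRUE)
  if (target_fs > rec$fs) stop("`target_fs` must not exceed the recording rate")
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop("`rec$fs` must be an integer multiple of `target_fs`")
  }
  factor <- round(factor)
  if (factor == 1L) return(rec)
  ntaps <- 16L * factor + 1L
  h <- signal::fir1(ntaps - 1L, 0.9 / factor, type = "low",
                    window = signal::hamming(ntaps))
  data <- t(apply(rec$data, 1L, apply_fir, h = h))
  keep <- seq(1L, ncol(data), by = factor)
  eeg_recording(data[, keep, drop = FALSE], fs = target_fs,
                channel_labels = rec$channel_labels, id = rec$id)
}

#' Band-pass filter a recording (zero-phase FIR, Hamming window)
#'
#' FIR band-pass designed with a Hamming window and applied without phase
#' distortion (delay-compensated linear phase). The filter order is three
#' periods of the low edge (`3 * fs / low`), a standard transition-width
#' heuristic.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @return The filtered recording.
#' @export
bandpass_fir <- function(rec, low = 0.5, high = 40) {
  fs <- rec$fs
  if (low <= 0 || low >= high || high >= fs / 2) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  ntaps <- 2L * round(1.5 * fs / low) + 1L   # ~3 periods of the low edge, odd
  h <- signal::fir1(ntaps - 1L, c(low, high) / (fs / 2), type = "pass",
                    window = signal::hamming(ntaps))
  data <- t(apply(rec$data, 1L, apply_fir, h = h))
  eeg_recording(data, fs = fs, channel_labels = rec$channel_labels,
                id = rec$id)
}

#' Flag bad channels
#'
#' Applies the three operationalized rejection criteria: flatline (absolute
#' successive differences below 1e-8 microvolts for more than `flatline_s`
#' seconds), highly correlating channel pairs (absolute correlation above
#' `corr_thresh`; the later-indexed channel of the pair is flagged), and
#' short-timed bursts (samples beyond `burst_sd` robust standard deviations
#' -- 1.4826 x MAD -- from the channel median). A reason code `drift` is
#' reserved but not populated.
#'
#' @param rec an [eeg_recording()].
#' @param config a [preproc_config()].
#' @return A `channel_mask` data frame: label, bad, reasons.
#' @export
detect_bad_channels <- function(rec, config = preproc_config()) {
  if (duration_s(rec) <= config$flatline_s) {
    stop("recording must be longer than the flatline criterion")
  }
  nc <- n_channels(rec)
  reasons <- vector("list", nc)
  for (i in seq_len(nc)) {
    x <- rec$data[i, ]
    r <- rle(abs(diff(x)) < 1e-8)
    runs <- r$lengths[r$values] + 1L          # samples spanned by a flat run
    if (length(runs) && max(runs) / rec$fs > config$flatline_s) {
      reasons[[i]] <- c(reasons[[i]], "flatline")
    }
    dev <- abs(x - stats::median(x))
    robust_sd <- stats::mad(x)
    if (robust_sd > 0 && any(dev > config$burst_sd * robust_sd)) {
      reasons[[i]] <- c(reasons[[i]], "burst")
    }
  }
  if (nc >= 2L) {
    cm <- suppressWarnings(stats::cor(t(rec$data)))
    for (j in 2:nc) {
      if (any(abs(cm[seq_len(j - 1L), j]) > config$corr_thresh, na.rm = TRUE)) {
        reasons[[j]] <- c(reasons[[j]], "correlated")
      }
    }
  }
  structure(
    data.frame(label = rec$channel_labels,
               bad = lengths(reasons) > 0L,
               reasons = vapply(reasons, function(r)
                 paste(r, collapse = ";"), "")),
    class = c("channel_mask", "data.frame")
  )
}

#' Replace bad channels by the mean of the good channels
#'
#' Bad channels are substituted by the sample-wise mean of all good
#' channels. This stands in for geometry-based spline interpolation, which
#' requires 3-D electrode positions that this pipeline does not model.
#'
#' @param rec an [eeg_recording()].
#' @param mask a `channel_mask` from [detect_bad_channels()].
#' @return The repaired recording.
#' @export
interpolate_bad <- function(rec, mask) {
  bad <- mask$bad
  if (length(bad) != n_channels(rec)) stop("mask length must match channel count")
  if (all(bad)) stop("unrecoverable recording: all channels flagged bad")
  if (!any(bad)) return(rec)
  fill <- colMeans(rec$data[!bad, , drop = FALSE])
  data <- rec$data
  data[bad, ] <- rep(fill, each = sum(bad))
  eeg_recording(data, rec$fs, rec$channel_labels, id = rec$id)
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean across channels, so the channel mean
#' is zero at every time point. Idempotent.
#'
#' @param rec an [eeg_recording()] with at least two channels.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  if (n_channels(rec) < 2L) stop("common average reference needs >= 2 channels")
  data <- sweep(rec$data, 2L, colMeans(rec$data))
  eeg_recording(data, rec$fs, rec$channel_labels, id = rec$id)
}

#' Clip a recording to a fixed duration
#'
#' Retains exactly `clip_s * fs` samples from the start.
#'
#' @param rec an [eeg_recording()].
#' @param clip_s target length in seconds; the recording must be at least
#'   this long.
#' @return The clipped recording.
#' @export
clip_duration <- function(rec, clip_s = 300) {
  n_keep <- round(clip_s * rec$fs)
  if (n_samples(rec) < n_keep) {
    stop(sprintf("insufficient data: %.1f s available, %.1f s requested",
                 duration_s(rec), clip_s))
  }
  if (n_samples(rec) == n_keep) return(rec)
  eeg_recording(rec$data[, seq_len(n_keep), drop = FALSE], rec$fs,
                rec$channel_labels, id = rec$id)
}

#' Select the frontal and occipital regions of interest
#'
#' Extracts the three frontal (Fz, F1, F2) and three occipital (Oz, O1, O2)
#' electrodes, matched case-insensitively, in the configured label order.
#'
#' @param rec an [eeg_recording()].
#' @param config a [preproc_config()].
#' @return List with 3-channel recordings `frontal` and `occipital`.
#' @export
select_rois <- function(rec, config = preproc_config()) {
  pick <- function(labels) {
    idx <- match(tolower(labels), tolower(rec$channel_labels))
    if (anyNA(idx)) {
      stop(sprintf("missing channel(s): %s",
                   paste(labels[is.na(idx)], collapse = ", ")))
    }
    eeg_recording(rec$data[idx, , drop = FALSE], rec$fs,
                  rec$channel_labels[idx], id = rec$id)
  }
  list(frontal = pick(config$frontal_labels),
       occipital = pick(config$occipital_labels))
}

#' Run the full pre-processing chain
#'
#' Order-fixed chain: downsample (when needed) -> band-pass FIR ->
#' bad-channel detection and repair -> common average reference -> clip to
#' `clip_s`. Returns the processed recording, the channel mask and the list
#' of applied steps.
#'
#' @param rec an [eeg_recording()].
#' @param config a [preproc_config()].
#' @return List with `recording`, `mask`, `steps`.
#' @export
preprocess_recording <- function(rec, config = preproc_config()) {
  steps <- character()
  if (rec$fs != config$target_fs) {
    rec <- downsample(rec, config$target_fs)
    steps <- c(steps, sprintf("downsample:%gHz", config$target_fs))
  }
  rec <- bandpass_fir(rec, config$band[1], config$band[2])
  steps <- c(steps, sprintf("bandpass:%g-%gHz", config$band[1], config$band[2]))
  mask <- detect_bad_channels(rec, config)
  rec <- interpolate_bad(rec, mask)
  steps <- c(steps, sprintf("bad_channels:%d", sum(mask$bad)))
  rec <- rereference_average(rec)
  steps <- c(steps, "rereference:common_average")
  rec <- clip_duration(rec, config$clip_s)
  steps <- c(steps, sprintf("clip:%gs", config$clip_s))
  list(recording = rec, mask = mask, steps = steps)
}
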