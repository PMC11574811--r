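#' Phenotype parameters for the synthetic EEG generator
#'
#' Describes one spectral/temporal EEG phenotype: a 1/f-type aperiodic
#' background with exponent `aperiodic_exponent`, an optional band-limited
#' oscillation (a Gaussian spectral bump at `oscillation_center_hz` with
#' bandwidth `oscillation_bandwidth_hz` and root-mean-square amplitude
#' `oscillation_amplitude` relative to the unit-variance background), and a
#' first-order autoregressive backbone with decay timescale `ar_timescale_s`
#' that sets the intrinsic timescale of the channel.
#'
#' The three stock phenotypes emulate the qualitative picture seen in
#' resting-state EEG of consciousness research: `control` (clear alpha bump
#' at 10 Hz, short timescale), `doc_theta` (weaker bump shifted into the
#' theta range, longer timescale), and `doc_flat` (no oscillatory bump,
#' steepest aperiodic decay, longest timescale).
#'
#' @param label one of `"control"`, `"doc_theta"`, `"doc_flat"`.
#' @param aperiodic_exponent slope of log power vs log frequency (>= 0).
#' @param oscillation_center_hz oscillation center in Hz (within 3--13 Hz),
#'   or `NA` for no oscillation.
#' @param oscillation_bandwidth_hz full bandwidth (2 SD) of the spectral
#'   bump in Hz.
#' @param oscillation_amplitude RMS amplitude of the oscillation relative to
#'   the unit-variance background; 0 disables it.
#' @param ar_timescale_s target autocorrelation decay timescale in seconds.
#' @return A `phenotype_params` list.
#' @export
phenotype_params <- function(label = c("control", "doc_theta", "doc_flat"),
                             aperiodic_exponent = NULL,
                             oscillation_center_hz = NULL,
                             oscillation_bandwidth_hz = NULL,
                             oscillation_amplitude = NULL,
                             ar_timescale_s = NULL) {
  label <- match.arg(label)
  defaults <- switch(label,
    control   = list(exp = 1.0, center = 10, bw = 2, amp = 1.2, tau = 0.03),
    doc_theta = list(exp = 1.5, center = 5,  bw = 2, amp = 0.8, tau = 0.06),
    doc_flat  = list(exp = 2.0, center = NA, bw = 2, amp = 0.0, tau = 0.09)
  )
  p <- list(
    label = label,
    aperiodic_exponent = aperiodic_exponent %||% defaults$exp,
    oscillation_center_hz = oscillation_center_hz %||% defaults$center,
    oscillation_bandwidth_hz = oscillation_bandwidth_hz %||% defaults$bw,
    oscillation_amplitude = oscillation_amplitude %||% defaults$amp,
    ar_timescale_s = ar_timescale_s %||% defaults$tau
  )
  if (p$aperiodic_exponent < 0) stop("`aperiodic_exponent` must be >= 0")
  if (p$ar_timescale_s <= 0) stop("`ar_timescale_s` must be positive")
  if (!is.na(p$oscillation_center_hz) &&
      (p$oscillation_center_hz < 3 || p$oscillation_center_hz > 13)) {
    stop("`oscillation_center_hz` must lie in [3, 13] Hz")
  }
  structure(p, class = "phenotype_params")
}

#' Simulate a 1/f-type aperiodic time series
#'
#' Spectral shaping of Gaussian white noise: the frequency-domain amplitude
#' is scaled by f^(-exponent/2), so the expected power spectrum follows
#' 1/f^exponent exactly. The DC component is zeroed and the series is
#' rescaled to zero mean and unit variance.
#'
#' @param duration_s duration in seconds (> 0).
#' @param fs sampling rate in Hz (> 0).
#' @param exponent aperiodic exponent (>= 0); 0 gives white noise.
#' @param seed RNG seed; the output is a pure function of (arguments, seed).
#' @return Numeric vector of length `round(duration_s * fs)`.
#' @export
simulate_aperiodic <- function(duration_s, fs, exponent, seed) {
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(exponent, "exponent")
  if (exponent < 0) stop("`exponent` must be >= 0")
  n <- round(duration_s * fs)
  if (n < 2) stop("`duration_s * fs` must give at least 2 samples")
  with_seed(seed, {
    w <- stats::rnorm(n)
    k <- 0:(n - 1)
    f <- pmin(k, n - k) * fs / n           # two-sided frequency axis
    scale <- c(0, f[-1]^(-exponent / 2))   # zero out DC
    x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
    x <- x - mean(x)
    x / stats::sd(x)
  })
}

#' Add a band-limited stochastic oscillation to a series
#'
#' The oscillation is band-pass-filtered noise: white noise multiplied, in
#' the frequency domain, by a Gaussian envelope centered at `center_hz` with
#' SD `bandwidth_hz / 2`. Unlike a pure sinusoid this produces a spectral
#' peak with a realistic, controllable width.
#'
#' @param series input time series.
#' @param fs sampling rate in Hz.
#' @param center_hz oscillation center (0 < center < fs/2).
#' @param bandwidth_hz full bandwidth (2 SD) of the spectral bump, > 0.
#' @param amplitude RMS amplitude of the added oscillation in the units of
#'   `series`; 0 returns the input unchanged.
#' @param seed RNG seed.
#' @return `series` plus the oscillation.
#' @export
add_band_oscillation <- function(series, fs, center_hz, bandwidth_hz,
                                 amplitude, seed) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(center_hz, "center_hz", positive = TRUE)
  if (center_hz >= fs / 2) stop("`center_hz` must be below the Nyquist frequency")
  stopifnot_scalar(bandwidth_hz, "bandwidth_hz", positive = TRUE)
  stopifnot_scalar(amplitude, "amplitude")
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (amplitude == 0) return(series)
  n <- length(series)
  with_seed(seed, {
    w <- stats::rnorm(n)
    k <- 0:(n - 1)
    f <- pmin(k, n - k) * fs / n
    env <- exp(-(f - center_hz)^2 / (2 * (bandwidth_hz / 2)^2))
    osc <- Re(stats::fft(stats::fft(w) * env, inverse = TRUE)) / n
    osc <- osc - mean(osc)
    series + osc * (amplitude / stats::sd(osc))
  })
}

#' Simulate a stationary AR(1) series
#'
#' First-order autoregressive process with lag-one coefficient `phi`,
#' initialized from its stationary distribution, with innovation variance
#' `1 - phi^2` so the series variance is 1. Its theoretical autocorrelation
#' at lag k is `phi^k`, making it the analytic oracle for the
#' autocorrelation-window statistics.
#'
#' @param phi lag-one coefficient, |phi| < 1.
#' @param n number of samples (> 1).
#' @param fs sampling rate in Hz (carried along for downstream use).
#' @param seed RNG seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_ar1 <- function(phi, n, fs = 250, seed = 1) {
  stopifnot_scalar(phi, "phi")
  if (abs(phi) >= 1) stop("`phi` must satisfy |phi| < 1 (stationarity)")
  stopifnot_scalar(n, "n", positive = TRUE)
  if (n < 2) stop("`n` must be > 1")
  with_seed(seed, {
    innov <- stats::rnorm(n, sd = sqrt(1 - phi^2))
    x0 <- stats::rnorm(1)                  # stationary initial state
    as.numeric(stats::filter(innov, phi, method = "recursive", init = x0))
  })
}

#' Simulate one synthetic EEG recording with known ground truth
#'
#' Each channel is an independent realization of the phenotype: a mixture of
#' an AR(1) backbone (70 % of background variance, lag-one coefficient
#' `exp(-1 / (fs * ar_timescale_s))`), aperiodic 1/f^exponent noise (30 %),
#' and the phenotype's band-limited oscillation, scaled to a typical EEG
#' amplitude of 20 microvolts RMS.
#'
#' @param phenotype a [phenotype_params()] object.
#' @param channel_labels labels; must contain Fz, F1, F2, Oz, O1, O2
#'   (case-insensitive).
#' @param fs sampling rate in Hz.
#' @param duration_s recording length in seconds.
#' @param seed RNG seed.
#' @param id recording identifier.
#' @param crs_r behavioral score 0--23 to record in the ground truth; for
#'   non-control phenotypes left `NULL` a seeded score is drawn.
#' @return List with elements `recording` (an [eeg_recording()]) and
#'   `truth` (phenotype, score and seed).
#' @export
simulate_subject <- function(phenotype,
                             channel_labels = c("Fz", "F1", "F2",
                                                "Oz", "O1", "O2", "Cz"),
                             fs = 250, duration_s = 300, seed = 1,
                             id = paste0("sub", seed), crs_r = NULL) {
  if (!inherits(phenotype, "phenotype_params")) {
    stop("`phenotype` must be a phenotype_params object")
  }
  required <- c("fz", "f1", "f2", "oz", "o1", "o2")
  missing <- setdiff(required, tolower(channel_labels))
  if (length(missing)) {
    stop(sprintf("channel labels must include the ROI electrodes; missing: %s",
                 paste(missing, collapse = ", ")))
  }
  n <- round(duration_s * fs)
  phi <- exp(-1 / (fs * phenotype$ar_timescale_s))
  n_ch <- length(channel_labels)
  data <- matrix(0, nrow = n_ch, ncol = n)
  for (i in seq_len(n_ch)) {
    ar <- simulate_ar1(phi, n, fs, seed = derive_seed(seed, 3 * i))
    ap <- simulate_aperiodic(duration_s, fs, phenotype$aperiodic_exponent,
                             seed = derive_seed(seed, 3 * i + 1))
    x <- sqrt(0.7) * ar + sqrt(0.3) * ap
    if (!is.na(phenotype$oscillation_center_hz) &&
        phenotype$oscillation_amplitude > 0) {
      x <- add_band_oscillation(x, fs,
                                center_hz = phenotype$oscillation_center_hz,
                                bandwidth_hz = phenotype$oscillation_bandwidth_hz,
                                amplitude = phenotype$oscillation_amplitude,
                                seed = derive_seed(seed, 3 * i + 2))
    }
    data[i, ] <- 20 * x                    # microvolt scale
  }
  if (is.null(crs_r) && phenotype$label != "control") {
    crs_r <- with_seed(derive_seed(seed, 999), sample(0:23, 1))
  }
  list(
    recording = eeg_recording(data, fs, channel_labels, id = id),
    truth = list(id = id, phenotype = phenotype,
                 crs_r = if (phenotype$label == "control") NA_integer_
                         else as.integer(crs_r),
                 seed = seed)
  )
}

#' Simulate a whole cohort with a built-in mediation structure
#'
#' Generates `n_control` control recordings and `n_mcs + n_uws` patient
#' recordings. Patients carry a latent chain with known path coefficients
#' `paths = c(a, b)`: a peak-power factor `x ~ N(0,1)`, a timescale factor
#' `m = a*x + noise_sd*e`, and a consciousness latent `y = b*m + noise_sd*e`
#' that is discretized to a CRS-R-like integer score 0--23. The timescale
#' factor maps monotonically to the channel autoregressive timescale
#' (higher `m`, shorter timescale) and the peak-power factor to oscillation
#' presence and amplitude, so the indirect effect `a*b` is recoverable from
#' the generated cohort. Patient group labels are assigned by score rank:
#' the `n_mcs` highest-scoring patients are labeled MCS, the rest UWS.
#'
#' Peaked patients receive a theta-range (5 Hz) oscillation, except the
#' highest peak-power fraction, which keeps an alpha-range (9 Hz)
#' oscillation; a small fraction of controls is generated as low-voltage
#' (no alpha bump), emulating the known LVEEG phenotype.
#'
#' @param n_control,n_mcs,n_uws cohort sizes (defaults mirror a 25/47/48
#'   design).
#' @param paths numeric length-2 vector `c(a, b)` of generating path
#'   coefficients.
#' @param noise_sd SD of the latent noise terms, > 0.
#' @param fs sampling rate in Hz.
#' @param duration_s recording length in seconds.
#' @param seed RNG seed.
#' @return List with `recordings` (list of [eeg_recording()]),
#'   `truth` (data frame with one row per recording: id, group, crs_r,
#'   phenotype label, oscillation parameters, timescale, and the latent
#'   factors `x_gt`, `m_gt`, `y_gt`), `paths` and `seed`.
#' @export
simulate_cohort <- function(n_control = 25, n_mcs = 47, n_uws = 48,
                            paths = c(0.6, 0.5), noise_sd = 0.8,
                            fs = 250, duration_s = 300, seed = 1) {
  if (n_control < 0 || n_mcs < 0 || n_uws < 0) stop("cohort counts must be >= 0")
  if (n_control + n_mcs + n_uws == 0) stop("at least one recording is required")
  stopifnot_scalar(noise_sd, "noise_sd", positive = TRUE)
  if (length(paths) != 2L || !is.numeric(paths)) {
    stop("`paths` must be a numeric vector c(a, b)")
  }
  a <- paths[1L]; b <- paths[2L]
  n_pat <- n_mcs + n_uws

  lat <- with_seed(derive_seed(seed, 1), {
    x <- stats::rnorm(n_pat)
    m <- a * x + noise_sd * stats::rnorm(n_pat)
    y <- b * m + noise_sd * stats::rnorm(n_pat)
    ctl_amp <- 1.2 + 0.15 * stats::rnorm(n_control)
    ctl_lv <- stats::runif(n_control) < 0.12   # low-voltage controls
    ctl_tau <- 0.03 * exp(0.15 * stats::rnorm(n_control))
    list(x = x, m = m, y = y,
         ctl_amp = ctl_amp, ctl_lv = ctl_lv, ctl_tau = ctl_tau)
  })
  score <- pmin(pmax(round(8 + 3.5 * lat$y), 0L), 23L)
  group <- rep("UWS", n_pat)
  if (n_pat > 0) group[order(score, seq_len(n_pat), decreasing = TRUE)[seq_len(n_mcs)]] <- "MCS"

  recordings <- vector("list", n_control + n_pat)
  rows <- vector("list", n_control + n_pat)
  k <- 0L
  for (i in seq_len(n_control)) {
    k <- k + 1L
    ph <- phenotype_params("control",
                           oscillation_amplitude =
                             if (lat$ctl_lv[i]) 0.05 else max(0.3, lat$ctl_amp[i]),
                           ar_timescale_s = lat$ctl_tau[i])
    sub <- simulate_subject(ph, fs = fs, duration_s = duration_s,
                            seed = derive_seed(seed, 100 + k),
                            id = sprintf("ctl%02d", i))
    recordings[[k]] <- sub$recording
    rows[[k]] <- data.frame(id = sub$truth$id, group = "control",
                            crs_r = NA_integer_, label = "control",
                            osc_center_hz = ph$oscillation_center_hz,
                            osc_amplitude = ph$oscillation_amplitude,
                            ar_timescale_s = ph$ar_timescale_s,
                            x_gt = NA_real_, m_gt = NA_real_, y_gt = NA_real_)
  }
  for (i in seq_len(n_pat)) {
    k <- k + 1L
    x_i <- lat$x[i]; m_i <- lat$m[i]
    tau_i <- min(max(0.06 * exp(-0.35 * m_i), 0.02), 0.2)
    if (x_i > 1.1) {                       # minority of patients keep alpha
      ph <- phenotype_params("doc_theta", oscillation_center_hz = 9,
                             oscillation_amplitude = 0.55 + 0.3 * x_i,
                             ar_timescale_s = tau_i)
    } else if (x_i > 0.1) {                # theta-shifted peak
      ph <- phenotype_params("doc_theta",
                             oscillation_amplitude = 0.55 + 0.3 * x_i,
                             ar_timescale_s = tau_i)
    } else {                               # flat spectrum
      ph <- phenotype_params("doc_flat", ar_timescale_s = tau_i)
    }
    sub <- simulate_subject(ph, fs = fs, duration_s = duration_s,
                            seed = derive_seed(seed, 100 + k),
                            id = sprintf("pat%02d", i), crs_r = score[i])
    recordings[[k]] <- sub$recording
    rows[[k]] <- data.frame(id = sub$truth$id, group = group[i],
                            crs_r = score[i], label = ph$label,
                            osc_center_hz = ph$oscillation_center_hz,
                            osc_amplitude = ph$oscillation_amplitude,
                            ar_timescale_s = ph$ar_timescale_s,
                            x_gt = x_i, m_gt = m_i, y_gt = lat$y[i])
  }
  truth <- do.call(rbind, rows)
  list(recordings = recordings, truth = truth, paths = c(a = a, b = b),
       seed = seed)
}
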