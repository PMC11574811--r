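#' Find interior local maxima of a sequence
#'
#' An index `i` is a local maximum when its value exceeds the neighboring
#' values. Plateaus (runs of equal values rising on the left and falling on
#' the right) count as a single maximum located at the plateau's first
#' index. Endpoints are never maxima. Indices are 1-based R positions.
#'
#' @param values numeric sequence of length >= 3.
#' @return Integer vector of maxima positions (possibly empty).
#' @export
find_local_maxima <- function(values) {
  n <- length(values)
  if (n < 3L) stop("sequence must have length >= 3")
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer())
  mid <- 2:(k - 1L)
  is_max <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  starts[mid][is_max]
}

#' Peak prominence
#'
#' Height of a peak above its highest flanking minimum: from the peak,
#' extend horizontally left and right until the signal end or a sample
#' strictly higher than the peak (the slope of a higher peak); take the
#' minimum on each side; prominence is the peak height minus the greater of
#' the two minima.
#'
#' @param values numeric sequence.
#' @param peak_index 1-based position of a local maximum in `values`.
#' @return Prominence, in the units of `values`.
#' @export
compute_prominence <- function(values, peak_index) {
  check_local_max(values, peak_index)
  h <- values[peak_index]
  side_min <- function(idx) {
    m <- Inf
    for (j in idx) {
      if (values[j] > h) break              # slope of a higher peak
      if (values[j] < m) m <- values[j]
    }
    m
  }
  left <- side_min(rev(seq_len(peak_index - 1L)))
  right <- side_min(seq(peak_index + 1L, length(values)))
  h - max(left, right)
}

check_local_max <- function(values, peak_index) {
  n <- length(values)
  if (peak_index < 2L || peak_index > n - 1L) {
    stop("`peak_index` must be an interior local maximum")
  }
  h <- values[peak_index]
  # previous distinct value must be lower; next distinct value must be lower
  left_ok <- values[peak_index - 1L] < h
  j <- peak_index + 1L
  while (j <= n && values[j] == h) j <- j + 1L
  right_ok <- j <= n && values[j] < h
  if (!left_ok || !right_ok) stop("`peak_index` is not a local maximum")
  invisible(TRUE)
}

#' Peak width at half prominence
#'
#' The horizontal reference line sits at the peak height minus half the
#' prominence; the width is the frequency-axis distance between the points
#' where the peak's descending slopes cross that line, located by linear
#' interpolation between grid points. A slope that leaves the grid before
#' crossing is clamped to the grid edge and flagged.
#'
#' @param values numeric sequence (log10 power).
#' @param grid frequency grid (Hz), same length, strictly increasing.
#' @param peak_index 1-based position of the peak.
#' @param prominence the peak's prominence (> 0).
#' @return List: `width`, `left_cross`, `right_cross`, `boundary` (TRUE if
#'   either crossing was clamped to the grid edge).
#' @export
compute_width <- function(values, grid, peak_index, prominence) {
  if (length(values) != length(grid)) stop("`values` and `grid` lengths differ")
  if (prominence <= 0) stop("`prominence` must be positive")
  h <- values[peak_index]
  ref <- h - prominence / 2
  n <- length(values)
  cross <- function(dir) {
    idx <- if (dir < 0) rev(seq_len(peak_index - 1L))
           else if (peak_index < n) seq(peak_index + 1L, n) else integer()
    prev <- peak_index
    for (j in idx) {
      if (values[j] > h) break              # higher peak: stop the trace
      if (values[j] <= ref) {
        frac <- (values[prev] - ref) / (values[prev] - values[j])
        return(list(x = grid[prev] + frac * (grid[j] - grid[prev]),
                    clamped = FALSE))
      }
      prev <- j
    }
    list(x = if (dir < 0) grid[1L] else grid[n], clamped = TRUE)
  }
  left <- cross(-1L)
  right <- cross(+1L)
  list(width = right$x - left$x, left_cross = left$x, right_cross = right$x,
       boundary = left$clamped || right$clamped)
}

#' Detect spectral peaks on a band-restricted log10 spectrum
#'
#' All local maxima of the log10 power with prominence at or above
#' `min_prominence` are candidates; among candidates closer than
#' `min_distance` on the frequency axis only the more prominent survives
#' (ties broken toward lower frequency). Widths and half-prominence
#' crossings are computed for the surviving peaks.
#'
#' @param psd a `psd_estimate`, already restricted to the analysis band,
#'   with finite log power.
#' @param min_prominence minimum peak prominence in log10-power units
#'   (default 0.1).
#' @param min_distance minimum distance between peaks in Hz (default 0.4).
#' @return A `spectral_peaks` data frame: index, frequency, height,
#'   prominence, width, left_cross, right_cross, boundary. Zero rows when
#'   no peak qualifies.
#' @export
detect_peaks <- function(psd, min_prominence = 0.1, min_distance = 0.4) {
  v <- psd$log_power
  if (any(!is.finite(v))) {
    stop("log power must be finite on the analysis band (restrict first)")
  }
  empty <- data.frame(index = integer(), frequency = numeric(),
                      height = numeric(), prominence = numeric(),
                      width = numeric(), left_cross = numeric(),
                      right_cross = numeric(), boundary = logical())
  class(empty) <- c("spectral_peaks", "data.frame")
  if (length(v) < 3L) return(empty)
  idx <- find_local_maxima(v)
  if (!length(idx)) return(empty)
  prom <- vapply(idx, function(i) compute_prominence(v, i), 0)
  keep <- prom >= min_prominence
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx)) return(empty)
  freq <- psd$freqs[idx]
  # greedy pruning: most prominent first, ties toward lower frequency
  ord <- order(-prom, freq)
  chosen <- integer()
  for (o in ord) {
    if (!length(chosen) || all(abs(freq[o] - freq[chosen]) >= min_distance)) {
      chosen <- c(chosen, o)
    }
  }
  chosen <- chosen[order(freq[chosen])]
  rows <- lapply(chosen, function(o) {
    w <- compute_width(v, psd$freqs, idx[o], prom[o])
    data.frame(index = idx[o], frequency = freq[o], height = v[idx[o]],
               prominence = prom[o], width = w$width,
               left_cross = w$left_cross, right_cross = w$right_cross,
               boundary = w$boundary)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("spectral_peaks", "data.frame")
  out
}

#' Classify the dominant peak into the alpha or theta band
#'
#' Among detected peaks with frequency in 3--13 Hz, the most prominent one
#' (ties toward lower frequency) is chosen and labeled `alpha` when its
#' frequency lies in \[7.5, 13\] Hz, `theta` when in \[3, 7.5) Hz. With no
#' candidate the spectrum counts as `none` (flat).
#'
#' @param peaks a `spectral_peaks` data frame from [detect_peaks()].
#' @return List: `band` (`"alpha"`, `"theta"` or `"none"`) and `peak`
#'   (the chosen one-row data frame, or `NULL`).
#' @export
classify_band <- function(peaks) {
  cand <- peaks[peaks$frequency >= 3 & peaks$frequency <= 13, , drop = FALSE]
  if (!nrow(cand)) return(list(band = "none", peak = NULL))
  best <- cand[order(-cand$prominence, cand$frequency)[1L], , drop = FALSE]
  band <- if (best$frequency >= 7.5) "alpha" else "theta"
  list(band = band, peak = best)
}

#' The seven spectral measures of one spectrum
#'
#' Maximum and minimum power are the extrema of the log10 power over the
#' analysis band. When a peak was chosen, its power (height), frequency,
#' prominence and width are reported together with the power ratio -- by
#' default the linear-scale ratio `10^(power - max_power)`, guaranteed to
#' lie in (0, 1]; `ratio = "log"` instead divides the two log10 values.
#' With no peak the extrema are still reported and the peak-derived fields
#' are `NA`.
#'
#' @param psd a band-restricted `psd_estimate`.
#' @param band band label from [classify_band()].
#' @param chosen chosen peak (one-row data frame) or `NULL`.
#' @param ratio `"linear"` (default) or `"log"`.
#' @return A one-row `peak_measures` data frame: band, power, frequency,
#'   prominence, width, max_power, min_power, power_ratio, boundary.
#' @export
spectral_measures <- function(psd, band, chosen, ratio = c("linear", "log")) {
  ratio <- match.arg(ratio)
  lp <- psd$log_power[is.finite(psd$log_power)]
  if (!length(lp)) stop("no finite log-power values on the analysis band")
  max_power <- max(lp)
  min_power <- min(lp)
  if (band == "none" || is.null(chosen)) {
    out <- data.frame(band = band, power = NA_real_, frequency = NA_real_,
                      prominence = NA_real_, width = NA_real_,
                      max_power = max_power, min_power = min_power,
                      power_ratio = NA_real_, boundary = NA)
  } else {
    pr <- if (ratio == "linear") 10^(chosen$height - max_power)
          else chosen$height / max_power
    out <- data.frame(band = band, power = chosen$height,
                      frequency = chosen$frequency,
                      prominence = chosen$prominence, width = chosen$width,
                      max_power = max_power, min_power = min_power,
                      power_ratio = pr, boundary = chosen$boundary)
  }
  class(out) <- c("peak_measures", "data.frame")
  out
}

#' Peak measures of a band-restricted spectrum, in one call
#'
#' Convenience wrapper chaining [detect_peaks()], [classify_band()] and
#' [spectral_measures()].
#'
#' @inheritParams detect_peaks
#' @inheritParams spectral_measures
#' @return A one-row `peak_measures` data frame.
#' @export
peak_measures <- function(psd, min_prominence = 0.1, min_distance = 0.4,
                          ratio = c("linear", "log")) {
  pk <- detect_peaks(psd, min_prominence, min_distance)
  cl <- classify_band(pk)
  spectral_measures(psd, cl$band, cl$peak, ratio = match.arg(ratio))
}
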