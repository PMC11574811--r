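test_that("local maxima are interior strict maxima with plateau-start rule", {
  expect_identical(find_local_maxima(c(0, 2, 1, 3, 0)), c(2L, 4L))
  expect_identical(find_local_maxima(c(5, 4, 3, 2, 1)), integer())
  expect_identical(find_local_maxima(c(0, 1, 1, 0)), 2L)
  expect_identical(find_local_maxima(c(1, 0, 1)), integer())  # endpoints never peak
  expect_error(find_local_maxima(c(1, 2)), "length")
})

test_that("prominence equals height above the highest flanking minimum", {
  v <- c(0, 2, 1, 3, 0)
  expect_equal(compute_prominence(v, 4), 3)
  expect_equal(compute_prominence(v, 2), 1)
  # single peak on a flat zero baseline: prominence is the full height
  expect_equal(compute_prominence(c(0, 0, 2.5, 0, 0), 3), 2.5)
  # worked example: peak -3.2 with highest minimum -3.7 -> 0.5
  v2 <- c(-3.5, -3.7, -3.2, -4.0, -3.8)
  expect_equal(compute_prominence(v2, 3), 0.5)
  expect_error(compute_prominence(v, 3), "not a local maximum")
})

test_that("width interpolates half-prominence crossings of the slopes", {
  # symmetric triangle over 8-12 Hz, apex at 10: crossings at 9 and 11
  grid <- seq(6, 14, by = 0.5)
  vals <- pmax(0, 2 - abs(grid - 10))
  i <- which.max(vals)
  p <- compute_prominence(vals, i)
  w <- compute_width(vals, grid, i, p)
  expect_equal(w$width, 2)
  expect_equal(w$left_cross, 9)
  expect_equal(w$right_cross, 11)
  expect_false(w$boundary)
  # a reference line below the traced segment clamps to the grid edge
  w2 <- compute_width(c(0.5, 1, 0), c(1, 2, 3), 2L, prominence = 2)
  expect_true(w2$boundary)
  expect_equal(w2$left_cross, 1)
  expect_error(compute_width(vals, grid, i, 0), "positive")
})

test_that("prominence and width match the brute-force oracle on random sequences", {
  set.seed(42)
  checked <- 0L
  for (rep in 1:200) {
    n <- sample(20:200, 1)
    v <- random_sequence(n)
    grid <- seq(0, by = 1 / 3, length.out = n)
    for (i in find_local_maxima(v)) {
      p <- compute_prominence(v, i)
      expect_equal(p, oracle_prominence(v, i))
      w <- compute_width(v, grid, i, p)
      expect_equal(w$width, oracle_width(v, grid, i, p))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 1000)
})

test_that("peak detection applies prominence and distance thresholds", {
  # monotone spectrum: no peaks
  psd <- make_psd(seq(0, -2, length.out = 30), seq(1, 30, length.out = 30))
  expect_equal(nrow(detect_peaks(psd)), 0)
  # prominence threshold semantics at 0.1
  base <- rep(-3, 21)
  lo <- base; lo[11] <- -2.95            # prominence 0.05
  hi <- base; hi[11] <- -2.85            # prominence 0.15
  f <- seq(5, 15, by = 0.5)
  expect_equal(nrow(detect_peaks(make_psd(lo, f))), 0)
  expect_equal(nrow(detect_peaks(make_psd(hi, f))), 1)
  # two maxima 0.3 Hz apart: only the more prominent survives
  f2 <- seq(9, 11, by = 0.1)
  v2 <- rep(-3, length(f2))
  v2[f2 == 9.7] <- -2.8                  # prominence 0.2
  v2[f2 == 10.0] <- -2.5                 # prominence 0.5
  pk <- detect_peaks(make_psd(v2, f2), min_distance = 0.4)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$frequency, 10)
  expect_equal(pk$prominence, 0.5)
})

test_that("raising the prominence threshold never adds peaks", {
  set.seed(7)
  for (rep in 1:25) {
    v <- random_sequence(80)
    psd <- make_psd(v, seq(1, 40, length.out = 80))
    loose <- detect_peaks(psd, min_prominence = 0.1)
    strict <- detect_peaks(psd, min_prominence = 0.5)
    expect_true(all(strict$index %in% loose$index))
  }
})

test_that("band classification picks the most prominent 3-13 Hz peak", {
  pk <- function(f, p) data.frame(index = 1L, frequency = f, height = -3,
                                  prominence = p, width = 1,
                                  left_cross = f - 1, right_cross = f + 1,
                                  boundary = FALSE)
  expect_equal(classify_band(pk(10, 0.3))$band, "alpha")
  expect_equal(classify_band(pk(5, 0.3))$band, "theta")
  expect_equal(classify_band(pk(7.5, 0.3))$band, "alpha")   # boundary to alpha
  both <- rbind(pk(5, 0.3), pk(10, 0.2))
  cl <- classify_band(both)
  expect_equal(cl$band, "theta")
  expect_equal(cl$peak$frequency, 5)
  expect_equal(classify_band(pk(20, 1))$band, "none")       # outside 3-13
  expect_equal(classify_band(pk(10, 0)[0, ])$band, "none")
})

test_that("spectral measures report extrema and the linear power ratio", {
  f <- seq(1, 30, length.out = 60)
  v <- -3.3 - 0.02 * f
  v[30] <- -3.48
  psd <- make_psd(v, f)
  # chosen peak 0.18 below the global maximum: ratio 10^(-0.18)
  chosen <- data.frame(index = 30L, frequency = f[30], height = -3.48,
                       prominence = 0.2, width = 1, left_cross = 0,
                       right_cross = 1, boundary = FALSE)
  m <- spectral_measures(psd, "alpha", chosen)
  expect_equal(m$max_power, max(v))
  expect_equal(m$min_power, min(v))
  expect_equal(m$power_ratio, 10^(-3.48 - max(v)), tolerance = 1e-12)
  # log-ratio variant stays available behind the switch
  m_log <- spectral_measures(psd, "alpha", chosen, ratio = "log")
  expect_equal(m_log$power_ratio, -3.48 / max(v))
  # peak at the global maximum: ratio exactly 1
  chosen2 <- transform(chosen, height = max(v))
  expect_equal(spectral_measures(psd, "alpha", chosen2)$power_ratio, 1)
  # no peak: extrema still reported, peak fields absent
  flat <- spectral_measures(psd, "none", NULL)
  expect_true(is.finite(flat$max_power) && is.finite(flat$min_power))
  expect_true(is.na(flat$power_ratio) && is.na(flat$power))
})

test_that("adding a constant to log power shifts heights but not shape measures", {
  set.seed(11)
  v <- random_sequence(90)
  f <- seq(1, 40, length.out = 90)
  m0 <- peak_measures(make_psd(v, f))
  m1 <- peak_measures(make_psd(v + 2.5, f))
  expect_equal(m1$band, m0$band)
  expect_equal(m1$frequency, m0$frequency)
  expect_equal(m1$prominence, m0$prominence)
  expect_equal(m1$width, m0$width)
  expect_equal(m1$power_ratio, m0$power_ratio)
  expect_equal(m1$power, m0$power + 2.5)
  expect_equal(m1$max_power, m0$max_power + 2.5)
  expect_equal(m1$min_power, m0$min_power + 2.5)
})
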