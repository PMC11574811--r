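test_that("generators are pure functions of parameters and seed", {
  expect_identical(simulate_aperiodic(10, 250, 1, seed = 3),
                   simulate_aperiodic(10, 250, 1, seed = 3))
  expect_identical(simulate_ar1(0.8, 1000, 250, seed = 3),
                   simulate_ar1(0.8, 1000, 250, seed = 3))
  s1 <- simulate_subject(phenotype_params("control"), duration_s = 8, seed = 5)
  s2 <- simulate_subject(phenotype_params("control"), duration_s = 8, seed = 5)
  expect_identical(s1$recording$data, s2$recording$data)
})

test_that("aperiodic synthesis reproduces the target log-log slope", {
  for (e in c(0, 1, 2)) {
    x <- simulate_aperiodic(300, 250, e, seed = 40 + e)
    expect_equal(length(x), 75000)
    expect_equal(mean(x), 0, tolerance = 1e-10)
    psd <- restrict_band(welch_psd(x, 250), 1, 40)
    slope <- unname(coef(lm(psd$log_power ~ log10(psd$freqs)))[2])
    expect_equal(slope, -e, tolerance = if (e == 0) 0.1 else 0.2)
  }
  expect_error(simulate_aperiodic(-1, 250, 1, seed = 1), "positive")
  expect_error(simulate_aperiodic(10, 250, -1, seed = 1), ">= 0")
})

test_that("band oscillations create detectable peaks that scale with amplitude", {
  bg <- simulate_aperiodic(120, 250, 1, seed = 8)
  expect_identical(add_band_oscillation(bg, 250, 10, 2, 0, seed = 1), bg)
  expect_error(add_band_oscillation(bg, 250, 200, 2, 1, seed = 1), "Nyquist")
  proms <- vapply(1:5, function(s) {
    vapply(c(0.5, 2), function(amp) {
      x <- add_band_oscillation(bg, 250, 10, 2, amp, seed = s)
      m <- peak_measures(restrict_band(welch_psd(x, 250), 0.5, 40))
      expect_equal(m$band, "alpha")
      expect_equal(m$frequency, 10, tolerance = 0.34)
      m$prominence
    }, 0)
  }, c(0, 0))
  expect_true(all(proms[2, ] > proms[1, ]))    # larger amplitude, larger prominence
})

test_that("AR(1) series have the stated lag-one correlation and bounds", {
  r1 <- function(x) cor(x[-1], x[-length(x)])
  expect_equal(r1(simulate_ar1(0.9, 75000, seed = 2)), 0.9, tolerance = 0.02)
  expect_equal(r1(simulate_ar1(0, 75000, seed = 2)), 0, tolerance = 0.02)
  expect_equal(sd(simulate_ar1(0.95, 75000, seed = 3)), 1, tolerance = 0.1)
  expect_error(simulate_ar1(1.0, 100, seed = 1), "stationarity")
})

test_that("subject phenotypes drive peak detection through the pipeline", {
  expect_error(simulate_subject(phenotype_params("control"),
                                channel_labels = c("Fz", "F1", "F2", "Oz", "O1")),
               "missing")
  sub <- simulate_subject(phenotype_params("control"), duration_s = 300,
                          seed = 1)
  expect_equal(ncol(sub$recording$data), 75000)
  roi_band <- function(label, seed) {
    s <- simulate_subject(phenotype_params(label), duration_s = 120, seed = seed)
    rois <- select_rois(s$recording)
    psd <- roi_average_psd(lapply(1:3, function(i)
      welch_psd(rois$frontal$data[i, ], 250)))
    peak_measures(restrict_band(psd, 0.5, 40))$band
  }
  ctl <- vapply(1:6, function(s) roi_band("control", s), "")
  flat <- vapply(1:6, function(s) roi_band("doc_flat", s), "")
  expect_gte(mean(ctl == "alpha"), 5 / 6)
  expect_lte(mean(flat != "none"), 1 / 6)
})

test_that("cohorts have the requested composition and ground-truth structure", {
  co <- simulate_cohort(n_control = 25, n_mcs = 47, n_uws = 48,
                        duration_s = 4, seed = 2)
  expect_length(co$recordings, 120)
  expect_equal(as.vector(table(co$truth$group)[c("control", "MCS", "UWS")]),
               c(25, 47, 48))
  expect_true(all(is.na(co$truth$crs_r[co$truth$group == "control"])))
  pat <- co$truth[co$truth$group != "control", ]
  expect_true(all(pat$crs_r >= 0 & pat$crs_r <= 23))
  # MCS drawn from the higher score range
  expect_gt(median(pat$crs_r[pat$group == "MCS"]),
            median(pat$crs_r[pat$group == "UWS"]))
  expect_error(simulate_cohort(0, 0, 0), "at least one")
})

test_that("generated cohorts carry a recoverable indirect effect", {
  # coverage of a*b = 0.30 by the 95% bootstrap CI across seeded cohorts
  hits <- vapply(1:20, function(s) {
    co <- simulate_cohort(n_control = 0, n_mcs = 100, n_uws = 100,
                          paths = c(0.6, 0.5), duration_s = 1, seed = s)
    med <- mediation_bootstrap(co$truth$x_gt, co$truth$m_gt, co$truth$crs_r,
                               n_boot = 600, seed = 4)
    med$ci_low <= 0.30 && 0.30 <= med$ci_high && med$ci_low > 0
  }, TRUE)
  expect_gte(mean(hits), 0.8)
  null <- simulate_cohort(n_control = 0, n_mcs = 100, n_uws = 100,
                          paths = c(0, 0), duration_s = 2, seed = 10)
  mednull <- mediation_bootstrap(null$truth$x_gt, null$truth$m_gt,
                                 null$truth$crs_r, n_boot = 1000, seed = 4)
  expect_true(mednull$ci_low <= 0 && 0 <= mednull$ci_high)
})
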