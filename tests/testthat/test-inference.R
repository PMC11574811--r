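test_that("the normality gate routes to t-test or Mann-Whitney", {
  set.seed(101)
  x <- rnorm(30); y <- rnorm(30, 0.2)
  # fixture check: both samples actually pass Shapiro-Wilk at 0.05
  expect_gt(shapiro.test(x)$p.value, 0.05)
  expect_gt(shapiro.test(y)$p.value, 0.05)
  expect_equal(normality_gated_compare(x, y)$test_name, "t-test")
  set.seed(7)
  xe <- rexp(40); ye <- rexp(40)
  expect_lt(shapiro.test(xe)$p.value, 0.05)
  expect_equal(normality_gated_compare(xe, ye)$test_name, "mann-whitney")
  # huge separation rejects under either branch
  expect_lt(normality_gated_compare(x + 10, y)$p_value, 0.001)
  expect_lt(normality_gated_compare(xe + 10, ye)$p_value, 0.001)
  expect_error(normality_gated_compare(1:2, y), "insufficient")
})

test_that("correlation gating honors the ordinal override", {
  x <- 1:10
  r <- correlate(x, x^2, force_ordinal = TRUE)
  expect_equal(r$estimate, 1)
  expect_equal(r$method, "spearman")
  expect_equal(correlate(x, -x)$estimate, -1)
  expect_equal(correlate(x, -x, force_ordinal = TRUE)$estimate, -1)
  set.seed(2)
  g <- rnorm(30)
  expect_equal(correlate(g, g + rnorm(30), force_ordinal = TRUE)$method,
               "spearman")
  expect_error(correlate(rep(1, 10), 1:10), "degenerate")
})

test_that("Benjamini-Hochberg adjustment is monotone and order-preserving", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(5)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("chi-square matches the textbook expected-count formula", {
  two <- rbind(c(10, 5, 5), c(4, 8, 8))
  r <- chi_square(two)
  exp_counts <- outer(rowSums(two), colSums(two)) / sum(two)
  expect_equal(r$statistic, sum((two - exp_counts)^2 / exp_counts),
               tolerance = 1e-9)
  expect_equal(r$df, 2)
  set.seed(31)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 20) + 1, 2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square(tab)$statistic, sum((tab - e)^2 / e),
                 tolerance = 1e-9)
  }
  expect_equal(chi_square(rbind(c(3, 4), c(3, 4)))$statistic, 0)
  expect_error(chi_square(rbind(c(1, 0), c(2, 0))), "zero row or column")
  expect_error(chi_square(matrix(1:3, 1)), "2x2")
})

test_that("quantile splits form contiguous near-equal rank groups", {
  g95 <- quantile_split(rnorm(95), 3)
  expect_equal(as.vector(table(g95)), c(32, 32, 31))
  expect_equal(quantile_split(c(1, 2, 3, 4), 2), c(1, 1, 2, 2))
  expect_equal(as.vector(table(quantile_split(rnorm(9), 3))), c(3, 3, 3))
  # contiguity in value order
  v <- rnorm(40)
  g <- quantile_split(v, 3)
  expect_true(all(diff(g[order(v)]) >= 0))
  expect_warning(quantile_split(rep(1, 6), 2), "identical")
  expect_error(quantile_split(1:2, 3), "at least one")
})

test_that("peak presence tables reflect the ACW-band construction", {
  tab <- data.frame(id = sprintf("s%02d", 1:30),
                    band = rep(c("alpha", "theta", "none"), each = 10),
                    acw0 = c(runif(10, 0.01, 0.03), runif(10, 0.04, 0.06),
                             runif(10, 0.07, 0.1)),
                    censored_acw0 = FALSE)
  ct <- peak_presence_by_split(tab, "acw0", 3)
  expect_equal(dim(ct), c(3L, 2L))
  expect_true(all(diff(ct[, "peak"]) <= 0))     # fewer peaks at longer ACW
  allpk <- transform(tab, band = "alpha")
  ct2 <- peak_presence_by_split(allpk, "acw0", 3)
  expect_true(all(ct2[, "no_peak"] == 0))
  expect_error(chi_square(ct2), "zero row or column")
  expect_identical(peak_presence_by_split(tab, "acw0", 3), ct)
})

test_that("bootstrap mediation recovers nulls, full mediation and is stable", {
  set.seed(12)
  n <- 300
  x <- rnorm(n)
  m_null <- rnorm(n)                    # b = 0 by construction
  y_null <- 0.5 * x + rnorm(n)
  null <- mediation_bootstrap(x, m_null, y_null, n_boot = 1000, seed = 3)
  expect_true(null$ci_low <= 0 && 0 <= null$ci_high)
  m <- x + rnorm(n)                     # complete mediation chain
  y <- m + rnorm(n)
  full <- mediation_bootstrap(x, m, y, n_boot = 1000, seed = 3)
  expect_lt(abs(full$c_direct), abs(full$c_total))
  expect_gt(full$ci_low, 0)
  expect_identical(mediation_bootstrap(x, m, y, n_boot = 500, seed = 9)$ab,
                   full$ab)
  # doubling the resamples moves the CI bounds by < 0.02
  xm <- 0.6 * x + 0.8 * rnorm(n)
  ym <- 0.5 * xm + 0.8 * rnorm(n)
  b1 <- mediation_bootstrap(x, xm, ym, n_boot = 2500, seed = 21)
  b2 <- mediation_bootstrap(x, xm, ym, n_boot = 5000, seed = 21)
  expect_lt(abs(b1$ci_low - b2$ci_low), 0.02)
  expect_lt(abs(b1$ci_high - b2$ci_high), 0.02)
  expect_error(mediation_bootstrap(x, x, y), "collinearity")
  expect_error(mediation_bootstrap(1:5, 1:5 + 0.5, rnorm(5)), "insufficient")
})
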