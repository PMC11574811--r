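toy_table <- function(n_per = 12, seed = 1) {
  set.seed(seed)
  g <- rep(c("control", "MCS", "UWS"), each = n_per)
  mu <- c(control = 3, MCS = 0.7, UWS = 0)[g]
  data.frame(id = sprintf("s%02d", seq_along(g)), roi = "occipital",
             group = g, band = ifelse(g == "control", "alpha",
                                      sample(c("alpha", "theta"),
                                             length(g), TRUE)),
             power = rnorm(length(g), mu), frequency = rnorm(length(g), 10),
             prominence = rnorm(length(g), mu, 0.5),
             width = rnorm(length(g), 2, 0.3),
             power_ratio = runif(length(g), 0.5, 1),
             max_power = rnorm(length(g)), min_power = rnorm(length(g), -4),
             acw50 = rnorm(length(g), 0.02 + 0.01 * (g != "control"), 0.003),
             acw_e = rnorm(length(g), 0.03 + 0.02 * (g != "control"), 0.005),
             acw0 = rnorm(length(g), 0.05 + 0.04 * (g != "control"), 0.01),
             censored_acw50 = FALSE, censored_acw_e = FALSE,
             censored_acw0 = FALSE)
}

test_that("feature assembly selects the stated columns and rows", {
  tab <- toy_table()
  fm <- build_features(tab, "combined", "three_class")
  expect_equal(ncol(fm$x), 10)
  expect_equal(ncol(build_features(tab, "alpha", "two_class")$x), 7)
  expect_equal(ncol(build_features(tab, "acw", "two_class")$x), 3)
  expect_setequal(levels(build_features(tab, "acw", "two_class")$y),
                  c("control", "DOC"))
  # rows without an alpha peak are excluded from alpha feature sets
  none <- tab; none$band[1] <- "none"
  fa <- build_features(none, "alpha", "three_class")
  expect_equal(nrow(fa$x), sum(none$band == "alpha"))
  allnone <- transform(tab, band = "none")
  expect_error(build_features(allnone, "alpha", "two_class"), "insufficient")
})

test_that("cross-validated OvO separates well-separated clusters", {
  fm <- build_features(toy_table(n_per = 20, seed = 3), "acw", "two_class")
  rep <- crossval_ovo(fm, k_folds = 10, seed = 2)
  expect_gte(rep$mean_accuracy, 0.95)
  expect_equal(sum(rep$confusion), nrow(fm$x))
  expect_equal(rep$n_binary, 1L)
  rep3 <- crossval_ovo(build_features(toy_table(n_per = 20, seed = 3),
                                      "combined", "three_class"),
                       k_folds = 5, seed = 2)
  expect_equal(rep3$n_binary, 3L)        # 3*2/2 binary models
  expect_equal(dim(rep3$confusion), c(3L, 3L))
})

test_that("fold assignment partitions the rows and is deterministic", {
  fm <- build_features(toy_table(n_per = 15, seed = 5), "acw", "three_class")
  r1 <- crossval_ovo(fm, k_folds = 5, seed = 7)
  r2 <- crossval_ovo(fm, k_folds = 5, seed = 7)
  expect_identical(r1$fold, r2$fold)
  expect_identical(r1$mean_accuracy, r2$mean_accuracy)
  expect_equal(sort(unique(r1$fold)), 1:5)
  expect_equal(length(r1$fold), nrow(fm$x))
  # stratification: each class appears in every fold
  expect_true(all(table(fm$y, r1$fold) > 0))
})

test_that("test rows never influence the training-fold scaler", {
  fm <- build_features(toy_table(n_per = 15, seed = 9), "acw", "two_class")
  base <- crossval_ovo(fm, k_folds = 5, seed = 4)
  out <- fm
  victim <- 1L
  out$x[victim, ] <- out$x[victim, ] * 1000   # extreme test-row outlier
  mod <- crossval_ovo(out, k_folds = 5, seed = 4)
  f <- base$fold[victim]
  same_fold_others <- setdiff(which(base$fold == f), victim)
  # rows sharing the outlier's test fold are scored by an untouched
  # training scaler and models, so their predictions cannot change
  expect_identical(base$predictions[same_fold_others],
                   mod$predictions[same_fold_others])
})

test_that("labels permuted at random give chance-level accuracy", {
  fm <- build_features(toy_table(n_per = 16, seed = 11), "acw", "two_class")
  accs <- vapply(1:10, function(s) {
    perm <- fm
    set.seed(s)
    perm$y <- factor(sample(as.character(fm$y)))
    suppressWarnings(crossval_ovo(perm, k_folds = 4, seed = s)$mean_accuracy)
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("confusion metrics follow the row/column conventions", {
  ident <- diag(c(5L, 8L, 3L))
  m <- report_metrics(ident)
  expect_true(all(m$precision == 1) && all(m$recall == 1) && all(m$f1 == 1))
  expect_equal(attr(m, "accuracy"), 1)
  # MCS: 6 of 15 correct; UWS: 3 of 5 correct
  cm <- rbind(MCS = c(6, 9), UWS = c(2, 3))
  colnames(cm) <- c("MCS", "UWS")
  m2 <- report_metrics(cm)
  expect_equal(m2$recall, c(6 / 15, 3 / 5))
  never <- rbind(c(4, 0), c(2, 0))
  expect_warning(m3 <- report_metrics(never), "0")
  expect_equal(m3$precision[2], 0)
  expect_error(report_metrics(matrix(1:6, 2)), "square")
})
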