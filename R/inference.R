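#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk is run on each sample at `alpha`; when both pass, a
#' two-sided independent (equal-variance) t-test is used, otherwise a
#' two-sided Mann-Whitney U test. The chosen branch is recorded.
#'
#' @param x,y numeric samples, each of size >= 3.
#' @param alpha significance level of the normality gate (default 0.05).
#' @return A `stat_result` list: `test_name`, `statistic`, `p_value`,
#'   `n` (group sizes), `normal` (per-sample gate outcome), `direction`
#'   (sign of mean(x) - mean(y)).
#' @export
normality_gated_compare <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) {
    stop("insufficient data: each sample needs n >= 3")
  }
  sw <- function(v) {
    # constant samples are trivially non-normal; Shapiro-Wilk is undefined
    if (stats::sd(v) == 0 || length(v) > 5000) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha
  }
  normal <- c(x = sw(x), y = sw(y))
  if (all(normal)) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    test_name <- "t-test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    test_name <- "mann-whitney"
  }
  stat_result(test_name, unname(ht$statistic), ht$p.value,
              n = c(length(x), length(y)), normal = normal,
              direction = sign(mean(x) - mean(y)))
}

stat_result <- function(test_name, statistic, p_value, ...) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, ...),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.4g, p = %.4g%s>\n", x$test_name,
              x$statistic, x$p_value,
              if (!is.null(x$estimate)) sprintf(", estimate = %.4g", x$estimate)
              else ""))
  invisible(x)
}

#' Normality-gated correlation
#'
#' Spearman when `force_ordinal = TRUE` (used for every correlation
#' involving an ordinal score); otherwise Pearson when both samples pass
#' Shapiro-Wilk at `alpha`, Spearman when either fails.
#'
#' @param x,y equal-length numeric samples, n >= 4.
#' @param force_ordinal force Spearman regardless of normality.
#' @param alpha significance level of the normality gate.
#' @return A `stat_result` with `estimate` (the coefficient) and
#'   `method` (`"pearson"` or `"spearman"`).
#' @export
correlate <- function(x, y, force_ordinal = FALSE, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("insufficient data: n >= 4 required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate sample: constant input")
  }
  gate <- function(v) length(v) <= 5000 && stats::shapiro.test(v)$p.value > alpha
  method <- if (force_ordinal) "spearman"
            else if (gate(x) && gate(y)) "pearson"
            else "spearman"
  ht <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  stat_result(paste0(method, " correlation"), unname(ht$statistic),
              ht$p.value, estimate = unname(ht$estimate), method = method,
              n = length(x))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values;
#' adjusted values are monotone, capped at 1, and order-preserving with the
#' input.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pearson chi-square test on a contingency table
#'
#' Chi-square without continuity correction, df = (rows-1)(cols-1). Rows
#' and columns with zero totals are rejected.
#'
#' @param table non-negative integer matrix (at least 2x2), e.g. groups x
#'   peak categories.
#' @return A `stat_result` with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("table must be at least 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column total")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  stat_result("chi-square", unname(ht$statistic), ht$p.value,
              df = unname(ht$parameter), expected = ht$expected,
              n = sum(table))
}

#' Rank-based quantile split
#'
#' Assigns values to `n_groups` contiguous rank groups of near-equal size
#' (remainder spread over the lowest groups, so n = 95 with 3 groups gives
#' sizes 32/32/31). Ties share the group of their stable sort position
#' (by value, then id).
#'
#' @param values numeric sample.
#' @param n_groups 2 (median split) or 3 (tertile split).
#' @param ids optional tie-breaking identifiers (defaults to input order).
#' @return Integer group assignment (1 = lowest values), aligned with the
#'   input order.
#' @export
quantile_split <- function(values, n_groups = 3, ids = seq_along(values)) {
  if (!n_groups %in% c(2L, 3L)) stop("`n_groups` must be 2 or 3")
  n <- length(values)
  if (n < n_groups) stop("need at least one value per group")
  if (length(unique(values)) == 1L) {
    warning("all values identical: split is arbitrary but deterministic")
  }
  sizes <- rep(n %/% n_groups, n_groups)
  rem <- n %% n_groups
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ord <- order(values, ids)
  groups <- integer(n)
  groups[ord] <- rep(seq_len(n_groups), times = sizes)
  groups
}

#' Peak presence by autocorrelation-window quantile
#'
#' Splits the rows of a subject table into ACW quantile groups and counts
#' peak presence/absence per group, producing a contingency table ready for
#' [chi_square()]. Rows with a censored value of the chosen measure are
#' excluded.
#'
#' @param table a subject table (see [build_subject_table()]).
#' @param acw_measure `"acw50"`, `"acw_e"` or `"acw0"`.
#' @param n_groups number of quantile groups (default 3).
#' @return Integer matrix `n_groups` x 2 (`peak`, `no_peak`).
#' @export
peak_presence_by_split <- function(table, acw_measure = "acw0",
                                   n_groups = 3) {
  cens_col <- paste0("censored_", acw_measure)
  keep <- !is.na(table[[acw_measure]])
  if (cens_col %in% names(table)) keep <- keep & !table[[cens_col]]
  tab <- table[keep, , drop = FALSE]
  g <- quantile_split(tab[[acw_measure]], n_groups, ids = tab$id)
  present <- tab$band != "none"
  out <- t(vapply(seq_len(n_groups), function(k)
    c(peak = sum(present[g == k]), no_peak = sum(!present[g == k])),
    c(peak = 0, no_peak = 0)))
  rownames(out) <- paste0("Q", seq_len(n_groups))
  out
}

#' Bootstrap mediation analysis (product of coefficients)
#'
#' All three variables are standardized; the `a` path is the OLS slope of
#' `m ~ x`, `b` and the direct effect come from `y ~ m + x`, the total
#' effect from `y ~ x`, and the indirect effect is `ab = a * b`. The
#' percentile confidence interval and a two-sided bootstrap p-value come
#' from `n_boot` case resamples (variables re-standardized within each
#' resample).
#'
#' @param x,m,y equal-length samples (independent variable, mediator,
#'   outcome), n >= 10.
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param conf confidence level of the percentile interval (default 0.95).
#' @return A `mediation_result` list: `a`, `b`, `c_total`, `c_direct`,
#'   `ab`, `ci_low`, `ci_high`, `p_ab`, `n_boot`, `n`, `seed`.
#' @export
mediation_bootstrap <- function(x, m, y, n_boot = 5000, seed = 1,
                                conf = 0.95) {
  ok <- stats::complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop("insufficient data: n >= 10 required")
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0) {
    stop("degenerate sample: constant variable")
  }
  if (abs(stats::cor(x, m)) > 0.999) {
    stop("collinearity: |cor(x, m)| > 0.999")
  }
  paths <- function(x, m, y) {
    r_xm <- stats::cor(x, m); r_xy <- stats::cor(x, y); r_my <- stats::cor(m, y)
    denom <- 1 - r_xm^2
    if (denom < 1e-12 || !is.finite(denom)) return(rep(NA_real_, 4L))
    b <- (r_my - r_xy * r_xm) / denom
    c_direct <- (r_xy - r_my * r_xm) / denom
    c(a = r_xm, b = b, c_total = r_xy, c_direct = c_direct)
  }
  pt <- paths(x, m, y)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]; mb <- m[idx]; yb <- y[idx]
      if (stats::sd(xb) == 0 || stats::sd(mb) == 0 || stats::sd(yb) == 0) {
        return(NA_real_)
      }
      p <- paths(xb, mb, yb)
      p[["a"]] * p[["b"]]
    }, 0)
  })
  boot <- boot[!is.na(boot)]
  ci <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  p_ab <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  structure(list(a = unname(pt[["a"]]), b = unname(pt[["b"]]),
                 c_total = unname(pt[["c_total"]]),
                 c_direct = unname(pt[["c_direct"]]),
                 ab = unname(pt[["a"]] * pt[["b"]]),
                 ci_low = ci[1L], ci_high = ci[2L], p_ab = p_ab,
                 n_boot = length(boot), n = n, seed = seed),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(paste0("<mediation: a = %.3f, b = %.3f, ab = %.3f ",
                     "[%.3f, %.3f], p = %.4g; c' = %.3f, c = %.3f; ",
                     "n = %d, %d resamples>\n"),
              x$a, x$b, x$ab, x$ci_low, x$ci_high, x$p_ab,
              x$c_direct, x$c_total, x$n, x$n_boot))
  invisible(x)
}
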