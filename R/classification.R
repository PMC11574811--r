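#' Assemble a feature matrix from a subject table
#'
#' Each ROI row of the subject table is one datapoint (frontal and
#' occipital rows are pooled). The `alpha` set keeps the rows with an
#' alpha-band peak and uses the five peak measures plus the two spectral
#' extrema (7 columns); the `acw` set uses the three autocorrelation
#' windows of every non-censored row (3 columns); `combined` uses all 10 on
#' alpha rows. For the two-class task MCS and UWS collapse into DOC.
#'
#' @param table a subject table (see [build_subject_table()]).
#' @param feature_set `"alpha"`, `"acw"` or `"combined"`.
#' @param task `"two_class"` (control vs DOC) or `"three_class"`
#'   (control vs MCS vs UWS).
#' @return A `feature_matrix` list: `x` (numeric matrix), `y` (factor of
#'   labels), `feature_set`, `task`.
#' @export
build_features <- function(table,
                           feature_set = c("alpha", "acw", "combined"),
                           task = c("two_class", "three_class")) {
  feature_set <- match.arg(feature_set)
  task <- match.arg(task)
  peak_cols <- c("power", "frequency", "prominence", "width", "power_ratio",
                 "max_power", "min_power")
  acw_cols <- c("acw50", "acw_e", "acw0")
  cols <- switch(feature_set, alpha = peak_cols, acw = acw_cols,
                 combined = c(peak_cols, acw_cols))
  rows <- if (feature_set == "acw") rep(TRUE, nrow(table))
          else table$band == "alpha"
  cens <- grep("^censored_", names(table), value = TRUE)
  if (length(cens)) rows <- rows & !Reduce(`|`, table[cens])
  sub <- table[rows, , drop = FALSE]
  sub <- sub[stats::complete.cases(sub[cols]), , drop = FALSE]
  if (!nrow(sub)) stop("insufficient data: no rows left for this feature set")
  y <- sub$group
  if (task == "two_class") y[y %in% c("MCS", "UWS")] <- "DOC"
  structure(list(x = as.matrix(sub[cols]), y = factor(y),
                 feature_set = feature_set, task = task),
            class = "feature_matrix")
}

#' Cross-validated one-vs-one maximum-margin classification
#'
#' Stratified k-fold cross-validation of a one-vs-one (OvO) multiclass
#' scheme: per fold, features are standardized with the training-fold
#' means/SDs only, N(N-1)/2 binary linear support vector machines (unit box
#' constraint) are trained on each class pair, and test rows are decoded by
#' majority vote (ties broken by the summed signed decision values, then by
#' class order). Accuracy, precision, recall and F1 are averaged across
#' folds; the confusion matrix is pooled; AUC is the macro average of the
#' one-vs-rest rank AUCs of the pooled per-class vote scores.
#'
#' @param features a `feature_matrix` from [build_features()].
#' @param k_folds requested number of folds (default 10); reduced with a
#'   warning when the smallest class is smaller.
#' @param seed RNG seed for the fold assignment.
#' @param cost box constraint of the binary classifiers (default 1).
#' @param kernel kernel of the binary classifiers (default `"linear"`).
#' @return A `classification_report` list: `fold_accuracy`,
#'   `mean_accuracy`, `sd_accuracy`, `per_class` (precision/recall/F1
#'   averaged over folds), `macro_auc`, `confusion` (pooled), `k_folds`,
#'   `seed`.
#' @export
crossval_ovo <- function(features, k_folds = 10, seed = 1, cost = 1,
                         kernel = "linear") {
  x <- features$x
  y <- features$y
  classes <- levels(y)
  if (length(classes) < 2L) stop("at least two classes are required")
  counts <- table(y)
  if (min(counts) < 2L) stop("every class needs at least 2 members")
  k <- min(k_folds, min(counts))
  if (k < k_folds) {
    warning(sprintf("folds reduced from %d to %d (smallest class has %d members)",
                    k_folds, k, min(counts)))
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  fold_acc <- numeric(k)
  fold_prec <- fold_rec <- fold_f1 <- matrix(NA_real_, k, length(classes),
                                             dimnames = list(NULL, classes))
  scores_all <- matrix(0, nrow(x), length(classes),
                       dimnames = list(NULL, classes))
  predictions <- character(nrow(x))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1
    xs_tr <- scale(x[tr, , drop = FALSE], mu, sdv)
    xs_te <- scale(x[te, , drop = FALSE], mu, sdv)
    votes <- matrix(0L, sum(te), length(classes),
                    dimnames = list(NULL, classes))
    score <- matrix(0, sum(te), length(classes),
                    dimnames = list(NULL, classes))
    for (pr in pairs) {
      sel <- tr & y %in% pr
      y2 <- factor(as.character(y[sel]), levels = pr)
      fit <- e1071::svm(scale(x[sel, , drop = FALSE], mu, sdv), y2,
                        kernel = kernel, cost = cost, scale = FALSE)
      pred <- stats::predict(fit, xs_te, decision.values = TRUE)
      dv <- attr(pred, "decision.values")[, 1L]
      # decision value is positive toward the first level of the model
      first <- strsplit(colnames(attr(pred, "decision.values")), "/")[[1L]][1L]
      second <- setdiff(pr, first)
      ji <- cbind(seq_len(sum(te)), match(as.character(pred), classes))
      votes[ji] <- votes[ji] + 1L
      score[, first] <- score[, first] + dv
      score[, second] <- score[, second] - dv
    }
    pred_cls <- apply(cbind(votes, score), 1L, function(r) {
      v <- r[seq_along(classes)]
      s <- r[-seq_along(classes)]
      top <- which(v == max(v))
      if (length(top) > 1L) top <- top[which.max(s[top])]
      classes[top]
    })
    truth <- as.character(y[te])
    cm <- table(factor(truth, classes), factor(pred_cls, classes))
    confusion <- confusion + cm
    fold_acc[f] <- mean(pred_cls == truth)
    m <- confusion_metrics(cm, warn = FALSE)
    fold_prec[f, ] <- ifelse(colSums(cm) > 0, m$precision, NA)
    fold_rec[f, ] <- ifelse(rowSums(cm) > 0, m$recall, NA)
    fold_f1[f, ] <- ifelse(rowSums(cm) > 0 | colSums(cm) > 0, m$f1, NA)
    scores_all[te, ] <- score
    predictions[te] <- pred_cls
  }
  auc <- vapply(classes, function(cl)
    rank_auc(scores_all[, cl], y == cl), 0)
  per_class <- data.frame(
    class = classes,
    precision = colMeans(fold_prec, na.rm = TRUE),
    recall = colMeans(fold_rec, na.rm = TRUE),
    f1 = colMeans(fold_f1, na.rm = TRUE),
    auc = auc, row.names = NULL)
  structure(list(fold_accuracy = fold_acc, mean_accuracy = mean(fold_acc),
                 sd_accuracy = stats::sd(fold_acc), per_class = per_class,
                 macro_auc = mean(auc), confusion = confusion,
                 k_folds = k, seed = seed, fold = fold,
                 predictions = predictions, n_binary = length(pairs),
                 feature_set = features$feature_set, task = features$task),
            class = "classification_report")
}

# Mann-Whitney formulation of the ROC AUC (ties handled by midranks).
rank_auc <- function(score, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification (%s, %s): accuracy %.1f%% +/- %.1f%% over %d folds, macro AUC %.3f>\n",
              x$feature_set %||% "?", x$task %||% "?",
              100 * x$mean_accuracy, 100 * x$sd_accuracy, x$k_folds,
              x$macro_auc))
  print(x$confusion)
  invisible(x)
}

confusion_metrics <- function(confusion, warn = TRUE) {
  confusion <- as.matrix(confusion)
  tp <- diag(confusion)
  prec_den <- colSums(confusion)
  rec_den <- rowSums(confusion)
  if (warn && any(prec_den == 0 | rec_den == 0)) {
    warning("class never predicted or never present: metric reported as 0")
  }
  precision <- ifelse(prec_den > 0, tp / prec_den, 0)
  recall <- ifelse(rec_den > 0, tp / rec_den, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Per-class metrics of a pooled confusion matrix
#'
#' Precision is the column-wise TP/(TP+FP), recall the row-wise
#' TP/(TP+FN) (rows are true classes, columns predictions), F1 their
#' harmonic mean. Ratios with zero denominator are reported as 0 with a
#' warning.
#'
#' @param confusion square non-negative integer matrix.
#' @return Data frame with class, precision, recall, f1, plus overall
#'   accuracy as an attribute.
#' @export
report_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("counts must be non-negative")
  m <- confusion_metrics(confusion)
  out <- data.frame(class = rownames(confusion) %||%
                      paste0("class", seq_len(nrow(confusion))),
                    precision = unname(m$precision),
                    recall = unname(m$recall), f1 = unname(m$f1))
  attr(out, "accuracy") <- sum(diag(confusion)) / sum(confusion)
  out
}
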