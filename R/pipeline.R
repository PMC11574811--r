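#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis, with the study
#' defaults: 250 Hz, 0.5--40 Hz band, 3 s Welch windows with 50 % overlap,
#' peak thresholds 0.1 (prominence) / 0.4 Hz (distance), 20 s maximum
#' autocorrelation lag, 5000 mediation resamples, 10-fold cross-validation.
#'
#' @param n_control,n_mcs,n_uws synthetic cohort sizes.
#' @param paths generating mediation path coefficients `c(a, b)`.
#' @param noise_sd latent noise SD of the cohort generator.
#' @param duration_s recording length in seconds.
#' @param preproc a [preproc_config()].
#' @param window_s,overlap Welch segment length (s) and fractional overlap.
#' @param min_prominence,min_distance peak thresholds (log10 power, Hz).
#' @param max_lag_s maximum autocorrelation lag in seconds.
#' @param n_boot mediation bootstrap resamples.
#' @param k_folds cross-validation folds.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_control = 25, n_mcs = 47, n_uws = 48,
                            paths = c(0.6, 0.5), noise_sd = 0.8,
                            duration_s = 300,
                            preproc = preproc_config(clip_s = duration_s),
                            window_s = 3, overlap = 0.5,
                            min_prominence = 0.1, min_distance = 0.4,
                            max_lag_s = 20, n_boot = 5000, k_folds = 10,
                            seed = 1) {
  structure(list(n_control = n_control, n_mcs = n_mcs, n_uws = n_uws,
                 paths = paths, noise_sd = noise_sd,
                 duration_s = duration_s, preproc = preproc,
                 window_s = window_s, overlap = overlap,
                 min_prominence = min_prominence,
                 min_distance = min_distance, max_lag_s = max_lag_s,
                 n_boot = n_boot, k_folds = k_folds, seed = seed),
            class = "pipeline_config")
}

#' Analyze one recording: spectra, peaks and timescales per ROI
#'
#' Runs the pre-processing chain, selects the frontal and occipital ROIs,
#' and for each ROI computes the channel-averaged Welch spectrum restricted
#' to the analysis band, the seven spectral measures, and the ROI-averaged
#' autocorrelation-window triplet.
#'
#' @param rec an [eeg_recording()].
#' @param config a [pipeline_config()].
#' @return Data frame with one row per ROI (`frontal`, `occipital`).
#' @export
analyze_recording <- function(rec, config = pipeline_config()) {
  pp <- preprocess_recording(rec, config$preproc)
  rois <- select_rois(pp$recording, config$preproc)
  rows <- lapply(names(rois), function(roi) {
    r <- rois[[roi]]
    # a repaired channel equals the common average after re-referencing and
    # carries no independent signal: exclude it from the ROI statistics
    live <- which(apply(r$data, 1L, stats::var) > 1e-12)
    if (!length(live)) {
      stop(sprintf("recording '%s': no usable channel in ROI '%s'",
                   rec$id, roi))
    }
    psds <- lapply(live, function(i)
      welch_psd(r$data[i, ], r$fs, config$window_s, config$overlap))
    psd <- restrict_band(roi_average_psd(psds),
                         config$preproc$band[1], config$preproc$band[2])
    meas <- peak_measures(psd, config$min_prominence, config$min_distance)
    trip <- roi_average_acw(lapply(live, function(i)
      acw_triplet(r$data[i, ], r$fs, config$max_lag_s)))
    cbind(data.frame(id = rec$id, roi = roi), meas, trip)
  })
  do.call(rbind, rows)
}

#' Build the tidy subject table for a cohort
#'
#' One row per (recording, ROI) with group, CRS-R score, peak band, the
#' seven spectral measures and the three autocorrelation windows -- the
#' substrate of all inference and classification.
#'
#' @param recordings list of [eeg_recording()] objects.
#' @param meta data frame with columns `id`, `group`, `crs_r`.
#' @param config a [pipeline_config()].
#' @return The subject table (data frame).
#' @export
build_subject_table <- function(recordings, meta,
                                config = pipeline_config()) {
  rows <- lapply(recordings, analyze_recording, config = config)
  tab <- do.call(rbind, rows)
  i <- match(tab$id, meta$id)
  if (anyNA(i)) stop("metadata is missing some recording ids")
  tab <- cbind(data.frame(id = tab$id, roi = tab$roi,
                          group = meta$group[i], crs_r = meta$crs_r[i]),
               tab[, setdiff(names(tab), c("id", "roi")), drop = FALSE])
  rownames(tab) <- NULL
  tab
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates generation, pre-processing, spectral and timescale
#' extraction, and the downstream inference sequence: peak-occurrence
#' chi-square per ROI, control-vs-DOC contrasts on every measure with BH
#' adjustment per ROI family, ACW-vs-measure correlations, bootstrap
#' mediation (measured power -> ACW-e^-1 -> CRS-R on theta-peak patient
#' rows), ACW tertile splits with chi-square, a median split on ACW-e^-1,
#' and the six classification runs (three feature sets x two tasks).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the subject table, test
#'   tables and manifest are written as CSV.
#' @return A `pipeline_result` list: `table`, `truth`, `occurrence`,
#'   `contrasts`, `correlations`, `mediation`, `splits`, `classification`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  seed <- config$seed
  cohort <- simulate_cohort(config$n_control, config$n_mcs, config$n_uws,
                            paths = config$paths, noise_sd = config$noise_sd,
                            fs = config$preproc$target_fs,
                            duration_s = config$duration_s, seed = seed)
  tab <- build_subject_table(cohort$recordings, cohort$truth, config)
  tab$doc <- ifelse(tab$group == "control", "control", "DOC")

  measures <- c("power", "frequency", "prominence", "width", "power_ratio",
                "max_power", "min_power", "acw50", "acw_e", "acw0")

  # peak occurrence: control vs DOC x (alpha, theta, none), per ROI
  occurrence <- lapply(split(tab, tab$roi), function(d) {
    counts <- table(factor(d$doc, c("control", "DOC")),
                    factor(d$band, c("alpha", "theta", "none")))
    list(counts = unclass(counts), test = chi_square(counts))
  })

  # group contrasts with BH adjustment per ROI family
  contrasts <- do.call(rbind, lapply(split(tab, tab$roi), function(d) {
    res <- lapply(measures, function(mn) {
      x <- d[[mn]][d$doc == "control"]; y <- d[[mn]][d$doc == "DOC"]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 3 || length(y) < 3) return(NULL)
      r <- normality_gated_compare(x, y)
      data.frame(roi = d$roi[1], measure = mn, test = r$test_name,
                 statistic = r$statistic, p_value = r$p_value,
                 direction = r$direction)
    })
    res <- do.call(rbind, res)
    ok <- is.finite(res$p_value)        # degenerate contrasts carry NA
    res$p_adjusted <- NA_real_
    res$p_adjusted[ok] <- bh_adjust(res$p_value[ok])
    res
  }))
  rownames(contrasts) <- NULL

  # ACW vs spectral measures (rows with a peak), Spearman for CRS-R
  correlations <- do.call(rbind, lapply(split(tab, tab$roi), function(d) {
    dpk <- d[d$band != "none", , drop = FALSE]
    res <- lapply(c("power", "power_ratio", "prominence", "width",
                    "frequency", "max_power", "min_power"), function(mn) {
      if (sum(stats::complete.cases(dpk[[mn]], dpk$acw_e)) < 4) return(NULL)
      r <- tryCatch(correlate(dpk[[mn]], dpk$acw_e),
                    error = function(e) NULL)   # constant measure: skip
      if (is.null(r)) return(NULL)
      data.frame(roi = d$roi[1], pair = paste0(mn, "~acw_e"),
                 method = r$method, estimate = r$estimate,
                 p_value = r$p_value)
    })
    dcrs <- d[!is.na(d$crs_r), , drop = FALSE]
    for (an in c("acw50", "acw_e", "acw0")) {
      if (sum(stats::complete.cases(dcrs[[an]], dcrs$crs_r)) >= 4 &&
          stats::sd(dcrs$crs_r) > 0) {
        r <- correlate(dcrs[[an]], dcrs$crs_r, force_ordinal = TRUE)
        res <- c(res, list(data.frame(roi = d$roi[1],
                                      pair = paste0(an, "~crs_r"),
                                      method = r$method,
                                      estimate = r$estimate,
                                      p_value = r$p_value)))
      }
    }
    res <- do.call(rbind, res)
    ok <- is.finite(res$p_value)
    res$p_adjusted <- NA_real_
    res$p_adjusted[ok] <- bh_adjust(res$p_value[ok])
    res
  }))
  rownames(correlations) <- NULL

  # mediation on measured values: power -> ACW-e^-1 -> CRS-R, theta rows
  med_rows <- tab[tab$band == "theta" & !is.na(tab$crs_r), , drop = FALSE]
  mediation <- if (nrow(med_rows) >= 10) {
    mediation_bootstrap(med_rows$power, med_rows$acw_e, med_rows$crs_r,
                        n_boot = config$n_boot,
                        seed = derive_seed(seed, 7001))
  } else NULL

  # ACW tertile splits (patients), peak presence per quantile
  pat <- tab[tab$group != "control", , drop = FALSE]
  splits <- lapply(split(pat, pat$roi), function(d) {
    lapply(stats::setNames(nm = c("acw50", "acw_e", "acw0")), function(an) {
      ct <- peak_presence_by_split(d, an, n_groups = 3)
      test <- tryCatch(chi_square(ct), error = function(e) NULL)
      list(counts = ct, test = test)
    })
  })

  # classification: three feature sets x two tasks
  classification <- list()
  for (fset in c("alpha", "acw", "combined")) {
    for (task in c("two_class", "three_class")) {
      rep_name <- paste(fset, task, sep = "_")
      classification[[rep_name]] <- tryCatch(
        suppressWarnings(crossval_ovo(build_features(tab, fset, task),
                                      k_folds = config$k_folds,
                                      seed = derive_seed(seed, 8001))),
        error = function(e) NULL)
    }
  }

  manifest <- list(
    stages = c("simulate", "preprocess", "spectra", "peaks", "timescales",
               "inference", "classification"),
    seed = seed, n_recordings = length(cohort$recordings),
    bh_families = "per (roi x analysis block)",
    censored_rows = sum(tab$censored_acw0, na.rm = TRUE))

  result <- structure(list(table = tab, truth = cohort$truth,
                           occurrence = occurrence, contrasts = contrasts,
                           correlations = correlations,
                           mediation = mediation, splits = splits,
                           classification = classification,
                           manifest = manifest, config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) signif(col, 12) else col)
    df
  }
  utils::write.csv(fmt(result$table), file.path(out_dir, "subject_table.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt(result$contrasts), file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt(result$correlations),
                   file.path(out_dir, "correlations.csv"), row.names = FALSE)
  man <- result$manifest
  writeLines(c(paste("stage:", man$stages),
               sprintf("seed: %d", man$seed),
               sprintf("n_recordings: %d", man$n_recordings),
               sprintf("bh_families: %s", man$bh_families),
               sprintf("censored_rows: %d", man$censored_rows)),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d rows (%d recordings x 2 ROIs)>\n",
              nrow(x$table), x$manifest$n_recordings))
  for (roi in names(x$occurrence)) {
    t <- x$occurrence[[roi]]$test
    cat(sprintf("  %s peak occurrence: X2(%d) = %.2f, p = %.3g\n",
                roi, t$df, t$statistic, t$p_value))
  }
  if (!is.null(x$mediation)) {
    cat(sprintf("  mediation (power -> ACW-e^-1 -> CRS-R): ab = %.3f [%.3f, %.3f]\n",
                x$mediation$ab, x$mediation$ci_low, x$mediation$ci_high))
  }
  for (nm in names(x$classification)) {
    r <- x$classification[[nm]]
    if (!is.null(r)) {
      cat(sprintf("  %s: accuracy %.1f%% +/- %.1f%%\n", nm,
                  100 * r$mean_accuracy, 100 * r$sd_accuracy))
    }
  }
  invisible(x)
}
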