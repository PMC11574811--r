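#' Multichannel EEG recording
#'
#' Container for a multichannel time series: a channels x samples numeric
#' matrix (microvolts), its sampling rate and unique channel labels. This is
#' the raw input of every stage of the pipeline.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique, non-empty labels, one
#'   per row of `data`.
#' @param id recording identifier (used as key in exported tables).
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, id = "rec") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix")
  }
  stopifnot_scalar(fs, "fs", positive = TRUE)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("one channel label per row of `data` is required")
  }
  if (anyDuplicated(channel_labels) || any(!nzchar(channel_labels))) {
    stop("channel labels must be unique and non-empty")
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         id = as.character(id)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording '%s': %d channels x %d samples @ %g Hz (%.1f s)>\n",
              x$id, n_channels(x), n_samples(x), x$fs, duration_s(x)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Read an EEG recording from disk
#'
#' Supports the European Data Format (EDF, 16-bit) and a plain-text matrix
#' format: a delimited numeric table with channels as columns and a header
#' row of labels, accompanied by a `<path>.meta` sidecar with `fs` and `id`
#' key-value lines.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"` or `"matrix"`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      edf = "edf",
      csv = , tsv = , txt = , mat = "matrix",
      stop(sprintf("cannot infer recording format from extension '.%s'", ext))
    )
  }
  if (format == "edf") read_edf(path) else read_matrix_recording(path)
}

#' Write an EEG recording to disk
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @param format `"edf"` or `"matrix"` (text matrix plus `.meta` sidecar).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "matrix")) {
  format <- match.arg(format)
  if (format == "edf") write_edf(rec, path) else write_matrix_recording(rec, path)
  invisible(path)
}

read_matrix_recording <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) {
    stop(sprintf("missing sidecar metadata file '%s'", meta_path))
  }
  meta_lines <- readLines(meta_path, warn = FALSE)
  meta_lines <- meta_lines[nzchar(trimws(meta_lines))]
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = "="), ""))
  meta <- stats::setNames(as.list(vals), keys)
  if (is.null(meta$fs)) stop("sidecar metadata must provide `fs`")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  labels <- colnames(tab)
  if (anyDuplicated(labels)) stop("duplicated channel labels in matrix header")
  eeg_recording(t(as.matrix(tab)), fs = as.numeric(meta$fs),
                channel_labels = labels,
                id = meta$id %||% basename(path))
}

write_matrix_recording <- function(rec, path) {
  tab <- as.data.frame(t(rec$data))
  colnames(tab) <- rec$channel_labels
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines(c(sprintf("fs=%.10g", rec$fs), sprintf("id=%s", rec$id)),
             paste0(path, ".meta"))
  invisible(path)
}
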