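#' EEG recording container
#'
#' A light container for a multi-channel EEG recording: a channels x samples
#' numeric matrix together with its sampling rate and channel labels. All
#' preprocessing and feature-extraction functions in the package accept and
#' return this class.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of unique labels, one per channel.
#'   Defaults to `"ch1"`, `"ch2"`, ...
#' @param preprocessed Logical flag marking the recording as filtered /
#'   normalized.
#'
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `channel_labels` and `preprocessed`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(256), nrow = 2), fs = 128)
#' rec
eeg_recording <- function(data, fs, channel_labels = NULL, preprocessed = FALSE) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric channels x samples matrix.")
  }
  if (nrow(data) < 1L || ncol(data) < 1L) {
    abort("`data` needs at least one channel and one sample.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a positive sampling rate in Hz.")
  }
  channel_labels <- channel_labels %||% paste0("ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data)) {
    abort("`channel_labels` must have one entry per channel.")
  }
  if (anyDuplicated(channel_labels)) {
    abort("`channel_labels` must be unique.")
  }
  structure(
    list(
      data = data,
      fs = as.numeric(fs),
      channel_labels = as.character(channel_labels),
      preprocessed = isTRUE(preprocessed)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)%s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    if (x$preprocessed) ", preprocessed" else ""
  ))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Convert an EEG recording to a long tibble
#'
#' @param x An [eeg_recording()].
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `channel`, `value`.
#' @export
tidy.eeg_recording <- function(x, ...) {
  tibble::tibble(
    time_s = rep((seq_len(ncol(x$data)) - 1) / x$fs, each = nrow(x$data)),
    channel = rep(x$channel_labels, times = ncol(x$data)),
    value = as.vector(x$data)
  )
}

#' Read and write EEG recordings as CSV
#'
#' The interchange format is one `time_s` column followed by one column per
#' channel (header = channel label), sampled at a constant rate.
#'
#' @param rec An [eeg_recording()].
#' @param path File path.
#' @return `write_eeg_csv()` returns `rec` invisibly; `read_eeg_csv()` returns
#'   an [eeg_recording()].
#' @export
write_eeg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- tibble::as_tibble(t(rec$data), .name_repair = "minimal")
  names(df) <- rec$channel_labels
  df <- dplyr::bind_cols(
    tibble::tibble(time_s = (seq_len(ncol(rec$data)) - 1) / rec$fs), df
  )
  readr::write_csv(df, path)
  invisible(rec)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (names(df)[1] != "time_s" || ncol(df) < 2L) {
    abort("Expected a `time_s` column followed by one column per channel.")
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    abort("`time_s` must increase at a constant sampling interval.")
  }
  eeg_recording(
    t(as.matrix(df[, -1, drop = FALSE])),
    fs = 1 / mean(dt),
    channel_labels = names(df)[-1]
  )
}
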