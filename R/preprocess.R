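#' Zero-phase Butterworth bandpass filter
#'
#' Filters every channel with a 2nd-order Butterworth bandpass (12 dB/octave
#' per band edge) applied forward and backward, so the net response is
#' zero-phase with 24 dB/octave effective roll-off. The default 1-30 Hz band
#' retains the delta-to-beta range used for the spectral fatigue features.
#' Edge transients are controlled by reflect-padding each channel before
#' filtering.
#'
#' @param rec An [eeg_recording()].
#' @param band_low,band_high Passband edges in Hz; must satisfy
#'   `0 < band_low < band_high < fs/2`.
#' @param filter_order Butterworth order per pass (default 2).
#'
#' @return A filtered [eeg_recording()] (same dimensions).
#' @export
#' @examples
#' rec <- generate_eeg(fatigue_profile(), duration = 4, seed = 1)
#' filt <- bandpass_filter(rec)
bandpass_filter <- function(rec, band_low = 1, band_high = 30,
                            filter_order = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(band_low > 0 && band_low < band_high)) {
    abort("Need 0 < band_low < band_high.")
  }
  if (band_high >= nyq) {
    abort(sprintf(
      "`band_high` (%g Hz) must be below the Nyquist frequency (%g Hz).",
      band_high, nyq
    ))
  }
  bf <- signal::butter(filter_order, c(band_low, band_high) / nyq,
                       type = "pass")
  n <- ncol(rec$data)
  # reflect-pad so the forward-backward passes settle before the data start
  pad <- min(max(3 * length(bf$b), ceiling(rec$fs)), n - 1)
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1)]))
    yp <- signal::filtfilt(bf, xp)
    out[ch, ] <- yp[(pad + 1):(pad + n)]
  }
  eeg_recording(out, rec$fs, rec$channel_labels, preprocessed = TRUE)
}

#' Per-channel z-score normalization
#'
#' Equalizes channel amplitudes by transforming each channel to mean 0 and
#' standard deviation 1. Channels with zero variance cannot be scaled; they
#' are set to all zeros with a warning.
#'
#' @param rec An [eeg_recording()].
#' @return A normalized [eeg_recording()].
#' @export
normalize_channels <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    s <- sd(out[ch, ])
    if (s == 0 || !is.finite(s)) {
      warn(sprintf("Channel %s has zero variance; set to zero.",
                   rec$channel_labels[ch]))
      out[ch, ] <- 0
    } else {
      out[ch, ] <- (out[ch, ] - mean(out[ch, ])) / s
    }
  }
  eeg_recording(out, rec$fs, rec$channel_labels, preprocessed = TRUE)
}

#' Artifact and bad-channel rejection
#'
#' Applies two documented rules to a filtered, normalized recording:
#' transient samples whose absolute z-score exceeds `artifact_z_threshold`
#' are replaced by linear interpolation from the neighbouring clean samples,
#' and channels whose variance differs from the median channel variance by
#' more than a factor `bad_channel_variance_ratio` (in either direction) are
#' dropped.
#'
#' @param rec An [eeg_recording()].
#' @param artifact_z_threshold Absolute z-score above which a sample is
#'   treated as a motion artifact (default 5).
#' @param bad_channel_variance_ratio Variance ratio versus the median
#'   channel beyond which a channel is dropped (default 10).
#'
#' @return A list with elements `recording` (the cleaned [eeg_recording()])
#'   and `report`: a list with `dropped_channels` (character) and
#'   `interpolated` (tibble `channel`, `start`, `end`, sample indices of each
#'   repaired span).
#' @export
reject_artifacts <- function(rec, artifact_z_threshold = 5,
                             bad_channel_variance_ratio = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (artifact_z_threshold <= 0 || bad_channel_variance_ratio < 1) {
    abort("Thresholds must be positive (variance ratio >= 1).")
  }
  v <- apply(rec$data, 1, var)
  med <- stats::median(v)
  bad <- v > med * bad_channel_variance_ratio |
    v < med / bad_channel_variance_ratio
  if (all(bad)) abort("All channels rejected by the variance-ratio rule.")
  dropped <- rec$channel_labels[bad]
  data <- rec$data[!bad, , drop = FALSE]
  labels <- rec$channel_labels[!bad]
  n <- ncol(data)
  spans <- list()
  for (ch in seq_len(nrow(data))) {
    x <- data[ch, ]
    z <- (x - mean(x)) / sd(x)
    out_idx <- which(abs(z) > artifact_z_threshold)
    if (length(out_idx) == 0) next
    keep <- setdiff(seq_len(n), out_idx)
    data[ch, out_idx] <- approx(keep, x[keep], xout = out_idx, rule = 2)$y
    runs <- split(out_idx, cumsum(c(1, diff(out_idx) != 1)))
    spans[[length(spans) + 1]] <- tibble::tibble(
      channel = labels[ch],
      start = vapply(runs, min, integer(1)),
      end = vapply(runs, max, integer(1))
    )
  }
  interpolated <- if (length(spans)) {
    dplyr::bind_rows(spans)
  } else {
    tibble::tibble(channel = character(), start = integer(), end = integer())
  }
  list(
    recording = eeg_recording(data, rec$fs, labels, preprocessed = TRUE),
    report = list(dropped_channels = dropped, interpolated = interpolated)
  )
}

#' Full preprocessing chain
#'
#' Convenience wrapper: bandpass filter, z-score normalization, then
#' artifact/bad-channel rejection.
#'
#' @inheritParams bandpass_filter
#' @inheritParams reject_artifacts
#' @return As [reject_artifacts()]: a list with `recording` and `report`.
#' @export
preprocess_eeg <- function(rec, band_low = 1, band_high = 30,
                           filter_order = 2,
                           artifact_z_threshold = 5,
                           bad_channel_variance_ratio = 10) {
  rec |>
    bandpass_filter(band_low, band_high, filter_order) |>
    normalize_channels() |>
    reject_artifacts(artifact_z_threshold, bad_channel_variance_ratio)
}
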