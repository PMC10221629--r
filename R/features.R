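#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the recording is split into
#' Hamming-windowed segments of `window_s` seconds overlapping by
#' `overlap_frac`, each segment's one-sided periodogram is computed, and the
#' segments are averaged per channel. The spectrum is then restricted to
#' `band`. Scaling follows the usual power-per-Hz convention, so the
#' integral of the PSD over frequency approximates the signal variance.
#'
#' @param rec An [eeg_recording()].
#' @param window_s Segment length in seconds (default 2).
#' @param overlap_frac Fractional overlap between segments in `[0, 1)`
#'   (default 0.5).
#' @param band Length-2 numeric, the frequency band (Hz) to retain.
#'
#' @return An object of class `power_spectrum`: a list with `freqs` (Hz,
#'   ascending), `psd` (channels x frequencies matrix, power per Hz),
#'   `band`, and `channel_labels`.
#' @export
#' @examples
#' rec <- generate_eeg(fatigue_profile(), duration = 8, seed = 1)
#' spec <- welch_psd(rec)
#' spec
welch_psd <- function(rec, window_s = 2, overlap_frac = 0.5, band = c(1, 30)) {
  stopifnot(inherits(rec, "eeg_recording"))
  nwin <- round(window_s * rec$fs)
  if (nwin < 8) abort("Window must span at least 8 samples.")
  if (overlap_frac < 0 || overlap_frac >= 1) {
    abort("`overlap_frac` must be in [0, 1).")
  }
  n <- ncol(rec$data)
  if (n < nwin) abort("Recording is shorter than one Welch window.")
  step <- max(1L, round(nwin * (1 - overlap_frac)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))  # Hamming
  u <- sum(w^2)
  freqs <- (0:(nwin %/% 2)) * rec$fs / nwin
  psd <- matrix(0, nrow = nrow(rec$data), ncol = length(freqs))
  for (ch in seq_len(nrow(rec$data))) {
    acc <- numeric(length(freqs))
    for (s0 in starts) {
      seg <- rec$data[ch, s0:(s0 + nwin - 1)]
      seg <- (seg - mean(seg)) * w
      sp <- abs(fft(seg)[seq_along(freqs)])^2 / (rec$fs * u)
      # one-sided: double everything except DC (and Nyquist when present)
      sc <- rep(2, length(freqs))
      sc[1] <- 1
      if (nwin %% 2 == 0) sc[length(freqs)] <- 1
      acc <- acc + sp * sc
    }
    psd[ch, ] <- acc / length(starts)
  }
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) abort("`band` contains no frequency bins.")
  structure(
    list(freqs = freqs[keep], psd = psd[, keep, drop = FALSE],
         band = band, channel_labels = rec$channel_labels),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum> %d channels, %d bins over %.3g-%.3g Hz\n",
    nrow(x$psd), length(x$freqs), min(x$freqs), max(x$freqs)
  ))
  invisible(x)
}

#' @export
tidy.power_spectrum <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channel_labels, times = length(x$freqs)),
    freq_hz = rep(x$freqs, each = nrow(x$psd)),
    psd = as.vector(x$psd)
  )
}

#' Centroid frequency of a power spectrum
#'
#' The power-weighted mean frequency
#' \deqn{CF = \sum_i f_i P(f_i) / \sum_i P(f_i)}
#' over the retained band. It tracks where the bulk of spectral power sits
#' and rises as power migrates toward higher frequencies. Being a ratio, it
#' is invariant to any positive rescaling of the PSD and always lies inside
#' the range of the retained frequencies.
#'
#' @param freqs Numeric vector of frequencies (Hz), or a `power_spectrum`.
#' @param power Numeric vector of non-negative spectral power values (same
#'   length as `freqs`); ignored when `freqs` is a `power_spectrum`.
#'
#' @return For numeric input, a single Hz value; for a `power_spectrum`, a
#'   named vector with one centroid per channel.
#' @export
#' @examples
#' centroid_frequency(c(10, 20), c(1, 3))  # 17.5
centroid_frequency <- function(freqs, power = NULL) {
  if (inherits(freqs, "power_spectrum")) {
    spec <- freqs
    return(setNames(
      apply(spec$psd, 1, function(p) centroid_frequency(spec$freqs, p)),
      spec$channel_labels
    ))
  }
  check_psd(freqs, power)
  sum(freqs * power) / sum(power)
}

#' Power spectral entropy
#'
#' Shannon entropy of the spectral distribution. The PSD is first normalized
#' to a probability distribution \eqn{p_i = P(f_i)/\sum_j P(f_j)}, then
#' \deqn{PSE = -\sum_i p_i \log_2 p_i}
#' (zero bins contribute nothing). Normalization makes the value invariant
#' to PSD scale and bounds it in `[0, log2(n)]` for `n` bins; a single
#' concentrated peak gives 0 while a flat spectrum gives the maximum.
#'
#' @inheritParams centroid_frequency
#' @param normalized If `TRUE`, divide by `log2(n)` so the result lies in
#'   `[0, 1]` regardless of the number of bins.
#'
#' @return Entropy in bits (or a per-channel named vector for a
#'   `power_spectrum`).
#' @export
#' @examples
#' power_spectral_entropy(1:8, rep(1, 8))  # 3 bits
power_spectral_entropy <- function(freqs, power = NULL, normalized = FALSE) {
  if (inherits(freqs, "power_spectrum")) {
    spec <- freqs
    return(setNames(
      apply(spec$psd, 1, function(p) {
        power_spectral_entropy(spec$freqs, p, normalized)
      }),
      spec$channel_labels
    ))
  }
  check_psd(freqs, power)
  p <- power / sum(power)
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  if (normalized) h <- h / log2(length(power))
  h
}

check_psd <- function(freqs, power) {
  if (!is.numeric(freqs) || !is.numeric(power)) {
    abort("`freqs` and `power` must be numeric vectors.")
  }
  if (length(freqs) != length(power)) {
    abort("`freqs` and `power` must have equal length.")
  }
  if (any(power < 0)) abort("Spectral power must be non-negative.")
  if (all(power == 0)) {
    abort("All-zero spectrum: the feature is undefined.")
  }
  invisible(TRUE)
}

#' Spectral feature table for a recording or spectrum
#'
#' Computes centroid frequency and power spectral entropy for every channel.
#'
#' @param x An [eeg_recording()] or a `power_spectrum` from [welch_psd()].
#' @param normalized Passed to [power_spectral_entropy()].
#' @param ... For a recording, passed on to [welch_psd()].
#'
#' @return A tibble with columns `channel` (index), `channel_label`,
#'   `cf_hz`, `pse_bits`.
#' @export
extract_features <- function(x, normalized = FALSE, ...) {
  spec <- if (inherits(x, "eeg_recording")) welch_psd(x, ...) else x
  stopifnot(inherits(spec, "power_spectrum"))
  tibble::tibble(
    channel = seq_len(nrow(spec$psd)),
    channel_label = spec$channel_labels,
    cf_hz = unname(centroid_frequency(spec)),
    pse_bits = unname(power_spectral_entropy(spec, normalized = normalized))
  )
}

#' Select representative channels by principal component analysis
#'
#' Standardizes the sessions x channels feature matrix, computes its
#' principal components, and for each of the first `k` components returns
#' the channel carrying the largest absolute loading among the channels not
#' already selected (one representative channel per component, so `k` equal
#' to the channel count returns a permutation of all channels). Ties break
#' toward the lower channel index, and each component's loading vector is
#' given a deterministic sign (its largest-magnitude element made
#' positive), so the selection does not depend on the eigen-solver's sign
#' choice.
#'
#' @param feature_matrix Numeric matrix (or data frame), sessions x
#'   channels, at least 2 rows.
#' @param k Number of components/channels to select (default 2).
#'
#' @return Integer vector of length `k` of channel (column) indices.
#' @export
#' @examples
#' m <- cbind(rnorm(10), 3 * rnorm(10), rnorm(10, sd = 1e-3))
#' pca_select_channels(scale(m), k = 2)
pca_select_channels <- function(feature_matrix, k = 2) {
  m <- as.matrix(feature_matrix)
  if (!is.numeric(m)) abort("`feature_matrix` must be numeric.")
  if (nrow(m) < 2) abort("Need at least 2 sessions (rows).")
  if (k < 1 || k > ncol(m)) abort("`k` must be between 1 and the channel count.")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    # constant channels carry no variance; standardize only the varying ones
    m[, sds > 0] <- scale(m[, sds > 0, drop = FALSE])
    m[, sds == 0] <- 0
  } else {
    m <- scale(m)
  }
  pc <- prcomp(m, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  if (rank < k) {
    abort(sprintf("Matrix rank %d is below the requested k = %d components.",
                  rank, k))
  }
  selected <- integer(0)
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) load <- -load
    free <- setdiff(seq_len(ncol(m)), selected)
    top <- free[which.max(abs(load)[free])]  # first max = lowest index on ties
    selected <- c(selected, top)
  }
  selected
}
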