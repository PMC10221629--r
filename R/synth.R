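#' Latent fatigue profile for the synthetic generators
#'
#' Bundles the effect sizes that couple a latent fatigue level (on the 0-4
#' Fatigue Severity Scale) to the synthetic EEG spectrum and Stroop-task
#' reaction times. The defaults are calibrated to the packaged study tables:
#' between the first and fifth task sets the mean FSS rises by about 1.4
#' points while channel-7 centroid frequency rises by about 1 Hz, spectral
#' entropy by about 0.08 normalized bits, and congruent reaction times by
#' about 90 ms; the mean Stroop effect is about 230 ms.
#'
#' @param level Latent fatigue level in `[0, 4]`.
#' @param cf_gain Expected upward shift of the extracted centroid frequency,
#'   Hz per fatigue unit (>= 0).
#' @param pse_gain Expected increase of power spectral entropy, bits per
#'   fatigue unit (>= 0).
#' @param rt_base_ms Mean congruent reaction time at `level = 0`, ms.
#' @param rt_fatigue_slope_ms Added mean reaction time per fatigue unit, ms.
#' @param stroop_cost_ms Mean incongruent minus congruent reaction-time
#'   difference, ms (>= 0).
#'
#' @return An object of class `fatigue_profile`.
#' @export
#' @examples
#' fatigue_profile(level = 2)
fatigue_profile <- function(level = 0,
                            cf_gain = 0.7,
                            pse_gain = 0.06,
                            rt_base_ms = 886,
                            rt_fatigue_slope_ms = 60,
                            stroop_cost_ms = 230) {
  if (!is.numeric(level) || length(level) != 1L || level < 0 || level > 4) {
    abort("`level` must be a single value in [0, 4] (the FSS range).")
  }
  if (cf_gain < 0 || pse_gain < 0 || stroop_cost_ms < 0) {
    abort("`cf_gain`, `pse_gain` and `stroop_cost_ms` must be >= 0.")
  }
  if (rt_base_ms <= 0) abort("`rt_base_ms` must be positive.")
  structure(
    list(
      level = level, cf_gain = cf_gain, pse_gain = pse_gain,
      rt_base_ms = rt_base_ms, rt_fatigue_slope_ms = rt_fatigue_slope_ms,
      stroop_cost_ms = stroop_cost_ms
    ),
    class = "fatigue_profile"
  )
}

#' @export
print.fatigue_profile <- function(x, ...) {
  cat(sprintf(
    "<fatigue_profile> level %.2g | cf_gain %.2g Hz/u | pse_gain %.2g bit/u | rt %g + %g ms/u | stroop %g ms\n",
    x$level, x$cf_gain, x$pse_gain, x$rt_base_ms, x$rt_fatigue_slope_ms,
    x$stroop_cost_ms
  ))
  invisible(x)
}

# Target power-spectral envelope (power per Hz, arbitrary scale) at latent
# fatigue `level`: 1/f background plus theta/alpha/beta Gaussian bumps.
# Fatigue raises beta-band power (calibrated so the band centroid moves by
# ~cf_gain Hz per unit) and flattens the background exponent (raising
# spectral entropy).
synth_envelope <- function(freqs, level, cf_gain, pse_gain) {
  bump <- function(f, c, w) exp(-((f - c)^2) / (2 * w^2))
  chi <- max(0.4, 1 - 2 * pse_gain * level)
  base <- function(g_beta, c_alpha) {
    2 / pmax(freqs, 0.5)^chi +
      0.4 * bump(freqs, 6, 1.5) +
      1.0 * bump(freqs, c_alpha, 1.5) +
      g_beta * bump(freqs, 20, 4)
  }
  c_alpha <- 10 + 0.25 * level
  centroid <- function(g_beta) {
    s <- base(g_beta, c_alpha)
    keep <- freqs >= 1 & freqs <= 30
    sum(freqs[keep] * s[keep]) / sum(s[keep])
  }
  target <- centroid(0.15) + cf_gain * level
  if (target <= centroid(0.15) + 1e-12) {
    g_beta <- 0.15
  } else if (centroid(80) <= target) {
    g_beta <- 80
  } else {
    g_beta <- stats::uniroot(function(g) centroid(g) - target,
                             c(0.15, 80), tol = 1e-8)$root
  }
  base(g_beta, c_alpha)
}

#' Generate a synthetic multi-channel EEG recording
#'
#' Each channel is coloured noise shaped in the frequency domain: a `1/f`
#' background plus band-limited theta, alpha and beta components. Rising
#' latent fatigue shifts power toward the beta band and flattens the
#' background, so the extracted centroid frequency and power spectral
#' entropy increase, in expectation, with `profile$level`. This emulates the
#' statistical structure the downstream analysis assumes; it makes no claim
#' of biophysical realism.
#'
#' @param profile A [fatigue_profile()].
#' @param n_channels Number of channels (default 14, the study montage).
#' @param fs Sampling rate in Hz (default 128, the study rate).
#' @param duration Recording length in seconds.
#' @param seed Integer seed; required, so identical calls are bit-identical.
#'
#' @return An [eeg_recording()] of dimension `n_channels x (fs * duration)`.
#' @export
#' @examples
#' rec <- generate_eeg(fatigue_profile(level = 2), duration = 8, seed = 1)
#' dim(rec)
generate_eeg <- function(profile = fatigue_profile(),
                         n_channels = 14, fs = 128, duration = 60, seed) {
  if (missing(seed)) abort("`seed` is required for reproducible generation.")
  stopifnot(inherits(profile, "fatigue_profile"))
  if (n_channels < 1) abort("`n_channels` must be >= 1.")
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be a positive sampling rate.")
  if (!is.numeric(duration) || duration <= 0) {
    abort("`duration` must be a positive number of seconds.")
  }
  n <- round(fs * duration)
  set.seed(as.integer(seed))
  freqs <- seq(0, fs / 2, by = fs / n)           # rfft grid
  env <- synth_envelope(freqs, profile$level, profile$cf_gain, profile$pse_gain)
  env[1] <- 0                                     # no DC power
  amp <- sqrt(env)
  data <- matrix(0, nrow = n_channels, ncol = n)
  n_pos <- length(freqs)
  for (ch in seq_len(n_channels)) {
    z <- complex(real = rnorm(n_pos), imaginary = rnorm(n_pos)) * amp
    spec <- c(z, Conj(rev(z[2:(n - n_pos + 1)])))
    data[ch, ] <- Re(fft(spec, inverse = TRUE)) / sqrt(n)
  }
  eeg_recording(data, fs = fs)
}

#' Generate one synthetic Stroop-task session
#'
#' Trials are drawn from the 16 word-by-colour combinations (4 congruent, 12
#' incongruent). Reaction times follow a shifted lognormal whose mean grows
#' with the latent fatigue level and, on incongruent trials, by the Stroop
#' cost; a trial counts as responded only if the reaction time falls inside
#' the 2 s response window.
#'
#' @param profile A [fatigue_profile()].
#' @param n_trials Number of trials (default 40, the study design).
#' @param seed Integer seed; required.
#'
#' @return A tibble with one row per trial: `trial`, `word`, `colour`,
#'   `congruent`, `rt_ms`, `responded`.
#' @export
#' @examples
#' generate_stroop_session(fatigue_profile(level = 1), seed = 7)
generate_stroop_session <- function(profile = fatigue_profile(),
                                    n_trials = 40, seed) {
  if (missing(seed)) abort("`seed` is required for reproducible generation.")
  stopifnot(inherits(profile, "fatigue_profile"))
  if (!is.numeric(n_trials) || n_trials < 1) abort("`n_trials` must be >= 1.")
  set.seed(as.integer(seed))
  colours <- c("red", "green", "blue", "yellow")
  word <- sample(colours, n_trials, replace = TRUE)
  colour <- sample(colours, n_trials, replace = TRUE)
  congruent <- word == colour
  shift <- 300
  sdlog <- 0.35
  mean_rt <- profile$rt_base_ms +
    profile$rt_fatigue_slope_ms * profile$level +
    ifelse(congruent, 0, profile$stroop_cost_ms)
  meanlog <- log(pmax(mean_rt - shift, 1)) - sdlog^2 / 2
  rt <- shift + stats::rlnorm(n_trials, meanlog = meanlog, sdlog = sdlog)
  tibble::tibble(
    trial = seq_len(n_trials),
    word = word,
    colour = colour,
    congruent = congruent,
    rt_ms = rt,
    responded = rt <= 2000
  )
}

#' Generate a synthetic study cohort
#'
#' Simulates `n_subjects` participants each completing `n_sessions` task
#' sets. The latent fatigue level follows `schedule` (by default rising
#' linearly from 0.5 to 2 across sessions, mirroring the packaged study's
#' first-to-fifth-set FSS rise) plus a per-subject random offset. Each
#' subject-session yields an EEG recording, a Stroop session summary, and an
#' FSS label equal to the latent level plus observer noise, discretized to
#' the half-point grid and clamped to `[0, 4]`.
#'
#' @param n_subjects,n_sessions Cohort dimensions (study: 12 x 5).
#' @param schedule Numeric vector of latent fatigue levels per session
#'   (length `n_sessions`). Default `seq(0.5, 2, length.out = n_sessions)`.
#' @param profile Base [fatigue_profile()]; its `level` is overridden by the
#'   schedule.
#' @param fss_noise_sd Standard deviation of the observer noise added to the
#'   latent level before discretizing the FSS label. `0` makes the label the
#'   clamped latent level.
#' @param subject_sd Standard deviation of the per-subject fatigue offset.
#' @param include_eeg If `FALSE`, skip EEG generation (Stroop/FSS only).
#' @param n_channels,fs,duration,n_trials Passed to the per-session
#'   generators.
#' @param seed Integer seed; required.
#'
#' @return A tibble with one row per subject-session: `subject`, `session`,
#'   `level` (latent), `fss`, `congruent_mean_ms`, `incongruent_mean_ms`,
#'   `stroop_effect_ms`, and (if `include_eeg`) a list-column `eeg` of
#'   [eeg_recording()] objects.
#' @export
#' @examples
#' cohort <- generate_cohort(3, 2, duration = 4, seed = 3)
#' cohort[, c("subject", "session", "level", "fss", "stroop_effect_ms")]
generate_cohort <- function(n_subjects = 12, n_sessions = 5,
                            schedule = NULL,
                            profile = fatigue_profile(),
                            fss_noise_sd = 0.5,
                            subject_sd = 0.3,
                            include_eeg = TRUE,
                            n_channels = 14, fs = 128, duration = 60,
                            n_trials = 40, seed) {
  if (missing(seed)) abort("`seed` is required for reproducible generation.")
  if (n_subjects < 1 || n_sessions < 1) {
    abort("`n_subjects` and `n_sessions` must be >= 1.")
  }
  schedule <- schedule %||% seq(0.5, 2, length.out = n_sessions)
  if (length(schedule) != n_sessions) {
    abort("`schedule` must supply one latent level per session.")
  }
  set.seed(as.integer(seed))
  offsets <- rnorm(n_subjects, 0, subject_sd)
  sub_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, 2L * n_subjects * n_sessions),
    ncol = 2L
  )
  fss_noise <- rnorm(n_subjects * n_sessions, 0, fss_noise_sd)
  grid <- tidyr::expand_grid(subject = seq_len(n_subjects),
                             session = seq_len(n_sessions))
  rows <- purrr::pmap(
    list(grid$subject, grid$session, seq_len(nrow(grid))),
    function(i, s, k) {
      level <- min(max(schedule[s] + offsets[i], 0), 4)
      p <- profile
      p$level <- level
      trials <- generate_stroop_session(p, n_trials, seed = sub_seeds[k, 1])
      ok <- trials$responded
      con <- mean(trials$rt_ms[ok & trials$congruent])
      inc <- mean(trials$rt_ms[ok & !trials$congruent])
      fss <- min(max(round(2 * (level + fss_noise[k])) / 2, 0), 4)
      out <- tibble::tibble(
        subject = i, session = s, level = level, fss = fss,
        congruent_mean_ms = con, incongruent_mean_ms = inc,
        stroop_effect_ms = inc - con
      )
      if (include_eeg) {
        out$eeg <- list(generate_eeg(p, n_channels, fs, duration,
                                     seed = sub_seeds[k, 2]))
      }
      out
    }
  )
  dplyr::bind_rows(rows)
}

#' Extract spectral features for every recording in a cohort
#'
#' Runs each EEG recording in a [generate_cohort()] table through the
#' preprocessing chain (bandpass, normalization) and Welch spectral feature
#' extraction, returning one row per subject-session-channel.
#'
#' @param cohort A tibble with an `eeg` list-column, as from
#'   [generate_cohort()].
#' @param channels Integer channel indices to keep (default: all).
#' @param band Frequency band in Hz for the features.
#' @param window_s,overlap_frac Welch settings, see [welch_psd()].
#' @param preprocess If `TRUE` (default), bandpass-filter and normalize each
#'   recording to `band` before estimating spectra.
#'
#' @return A tibble: `subject`, `session`, `level`, `fss`, `channel`,
#'   `cf_hz`, `pse_bits`.
#' @export
cohort_features <- function(cohort, channels = NULL, band = c(1, 30),
                            window_s = 2, overlap_frac = 0.5,
                            preprocess = TRUE) {
  if (is.null(cohort$eeg)) abort("`cohort` has no `eeg` list-column.")
  purrr::pmap(
    list(cohort$subject, cohort$session, cohort$level, cohort$fss, cohort$eeg),
    function(subject, session, level, fss, rec) {
      if (preprocess) {
        rec <- normalize_channels(bandpass_filter(rec, band[1], band[2]))
      }
      spec <- welch_psd(rec, window_s = window_s,
                        overlap_frac = overlap_frac, band = band)
      feats <- extract_features(spec)
      if (!is.null(channels)) feats <- feats[feats$channel %in% channels, ]
      dplyr::bind_cols(
        tibble::tibble(subject = subject, session = session,
                       level = level, fss = fss),
        feats
      )
    }
  ) |>
    dplyr::bind_rows()
}
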