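test_that("bandpass keeps in-band signal and removes drift and DC", {
  inband <- sine_recording(10)
  out <- bandpass_filter(inband)
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(out$data), rms(inband$data), tolerance = 0.05)

  drift <- sine_recording(0.1)
  out_d <- bandpass_filter(drift)
  expect_lt(rms(out_d$data) / rms(drift$data), 0.10)

  dc <- eeg_recording(matrix(5, 1, 1024), 128)
  expect_lt(max(abs(bandpass_filter(dc)$data)), 0.05)
})

# direct evaluation of the designed transfer function H(e^{-iw}) at f Hz,
# independent of the filtering code path
butter_gain <- function(bf, f, fs) {
  w <- 2 * pi * f / fs
  zb <- exp(-1i * w * (seq_along(bf$b) - 1))
  za <- exp(-1i * w * (seq_along(bf$a) - 1))
  Mod(sum(bf$b * zb) / sum(bf$a * za))
}

test_that("achieved drift attenuation is consistent with the designed response", {
  # oracle: squared magnitude response of the designed filter (applied
  # forward and backward) at the drift frequency
  fs <- 128
  bf <- signal::butter(2, c(1, 30) / (fs / 2), type = "pass")
  predicted <- butter_gain(bf, 0.1, fs)^2
  expect_lt(predicted, 1e-3)
  drift <- sine_recording(0.1, duration = 60)
  achieved <- sqrt(mean(bandpass_filter(drift)$data^2)) /
    sqrt(mean(drift$data^2))
  # edge transients set the floor; achieved must not exceed 100x the
  # steady-state oracle
  expect_lt(achieved, predicted * 100 + 1e-3)
})

test_that("designed filter meets the passband/stopband template", {
  fs <- 128
  bf <- signal::butter(2, c(1, 30) / (fs / 2), type = "pass")
  gain_db <- function(f) 20 * log10(butter_gain(bf, f, fs))
  expect_gt(gain_db(10), -1)            # passband ripple < 1 dB
  expect_lt(gain_db(0.25), gain_db(10) - 12)
  expect_lt(gain_db(60), gain_db(10) - 12)
})

test_that("filtering is linear and zero-phase", {
  set.seed(4)
  x <- rnorm(1024)
  y <- rnorm(1024)
  fx <- bandpass_filter(eeg_recording(rbind(x), 128))$data[1, ]
  fy <- bandpass_filter(eeg_recording(rbind(y), 128))$data[1, ]
  fxy <- bandpass_filter(eeg_recording(rbind(2 * x - 3 * y), 128))$data[1, ]
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-8)

  sine <- sine_recording(10)
  filt <- bandpass_filter(sine)$data[1, ]
  cc <- ccf(sine$data[1, ], filt, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band edges are validated against Nyquist", {
  rec <- sine_recording(10)
  expect_error(bandpass_filter(rec, 1, 64), "Nyquist")
  expect_error(bandpass_filter(rec, 30, 1), "band_low")
})

test_that("normalization z-scores channels and is idempotent", {
  rec <- eeg_recording(rbind(c(1, 2, 3), c(10, 20, 40)), 128)
  norm <- normalize_channels(rec)
  expect_equal(rowMeans(norm$data), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(norm$data, 1, sd), c(1, 1), tolerance = 1e-12)
  again <- normalize_channels(norm)
  expect_equal(again$data, norm$data, tolerance = 1e-12)
})

test_that("constant channels normalize to zero with a warning", {
  rec <- eeg_recording(rbind(rep(7, 100), rnorm(100)), 128)
  expect_warning(norm <- normalize_channels(rec), "zero variance")
  expect_true(all(norm$data[1, ] == 0))
})

test_that("clean recordings pass artifact rejection untouched", {
  for (s in 1:5) {
    rec <- generate_eeg(fatigue_profile(level = 1), n_channels = 4,
                        duration = 8, seed = s)
    res <- preprocess_eeg(rec)
    expect_length(res$report$dropped_channels, 0)
    expect_equal(nrow(res$report$interpolated), 0L)
  }
})

test_that("high-variance channels are dropped and transients interpolated", {
  set.seed(8)
  data <- matrix(rnorm(4 * 1024), 4, 1024)
  data[2, ] <- data[2, ] * sqrt(50)               # 50x variance channel
  rec <- normalize_channels(bandpass_filter(eeg_recording(data, 128)))
  rec$data[2, ] <- rec$data[2, ] * sqrt(50)       # restore after z-scoring
  res <- reject_artifacts(rec)
  expect_identical(res$report$dropped_channels, "ch2")

  clean <- matrix(rnorm(2 * 1024), 2, 1024)
  clean[1, 500:503] <- 500                         # planted transient
  rec2 <- eeg_recording(clean, 128, preprocessed = TRUE)
  res2 <- reject_artifacts(rec2)
  spans <- res2$report$interpolated
  expect_true(any(spans$channel == "ch1" & spans$start <= 500 &
                    spans$end >= 503))
  expect_lt(max(abs(res2$recording$data[1, 500:503])), 10)
  # rejection never increases the channel count
  expect_lte(nrow(res2$recording$data), nrow(rec2$data))
})
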