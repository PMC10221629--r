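test_that("EEG generation has the requested shape and is seed-deterministic", {
  rec <- generate_eeg(fatigue_profile(level = 0), n_channels = 14, fs = 128,
                      duration = 60, seed = 1)
  expect_equal(dim(rec), c(14L, 7680L))
  rec2 <- generate_eeg(fatigue_profile(level = 0), n_channels = 14, fs = 128,
                       duration = 60, seed = 1)
  expect_identical(rec$data, rec2$data)
  rec3 <- generate_eeg(fatigue_profile(level = 0), n_channels = 14, fs = 128,
                       duration = 60, seed = 2)
  expect_false(identical(rec$data, rec3$data))
})

test_that("EEG generation validates its arguments", {
  expect_error(generate_eeg(fatigue_profile(), duration = 4), "seed")
  expect_error(generate_eeg(fatigue_profile(), duration = -1, seed = 1),
               "duration")
  expect_error(generate_eeg(fatigue_profile(), fs = 0, duration = 4, seed = 1),
               "fs")
  expect_error(fatigue_profile(level = 5), "\\[0, 4\\]")
  expect_error(fatigue_profile(cf_gain = -1), ">= 0")
})

test_that("extracted CF and PSE increase with the latent fatigue level", {
  feats_at <- function(level) {
    vals <- sapply(1:10, function(s) {
      rec <- generate_eeg(fatigue_profile(level = level), n_channels = 1,
                          duration = 8, seed = s)
      f <- extract_features(normalize_channels(bandpass_filter(rec)))
      c(f$cf_hz, f$pse_bits)
    })
    rowMeans(vals)
  }
  f0 <- feats_at(0)
  f2 <- feats_at(2)
  f4 <- feats_at(4)
  expect_gt(f2[1], f0[1])   # CF monotone in level
  expect_gt(f4[1], f2[1])
  expect_gt(f4[2], f0[2])   # PSE rises with level
})

test_that("Stroop sessions follow the 40-trial 16-combination design", {
  trials <- generate_stroop_session(fatigue_profile(), n_trials = 40, seed = 7)
  expect_equal(nrow(trials), 40L)
  expect_true(all(trials$rt_ms > 0))
  expect_identical(trials$responded, trials$rt_ms <= 2000)
  expect_setequal(unique(trials$congruent), c(TRUE, FALSE))
  # congruent iff word matches colour; both drawn from four colours
  expect_identical(trials$congruent, trials$word == trials$colour)
  expect_error(generate_stroop_session(fatigue_profile(), n_trials = 0,
                                       seed = 1), "n_trials")
  expect_error(generate_stroop_session(fatigue_profile(), n_trials = 40),
               "seed")
})

test_that("ensemble Stroop effect tracks the profile's interference cost", {
  effect <- function(profile, seeds) {
    mean(sapply(seeds, function(s) {
      tr <- generate_stroop_session(profile, n_trials = 40, seed = s)
      mean(tr$rt_ms[!tr$congruent]) - mean(tr$rt_ms[tr$congruent])
    }))
  }
  null_prof <- fatigue_profile(stroop_cost_ms = 0)
  expect_lt(abs(effect(null_prof, 1:40)), 20)
  # profile matched to a participant with congruent 790 ms / incongruent
  # 1118 ms: simulated effect should approach 328 ms in expectation
  p1 <- fatigue_profile(level = 0, rt_base_ms = 790, stroop_cost_ms = 328)
  expect_equal(effect(p1, 1:100), 328, tolerance = 30 / 328)
})

test_that("cohorts have one row per subject-session with gridded FSS labels", {
  cohort <- generate_cohort(12, 5, include_eeg = FALSE, seed = 3)
  expect_equal(nrow(cohort), 60L)
  expect_true(all(cohort$fss >= 0 & cohort$fss <= 4))
  expect_true(all((cohort$fss * 2) %% 1 == 0))  # half-point grid
  cohort2 <- generate_cohort(12, 5, include_eeg = FALSE, seed = 3)
  expect_identical(cohort, cohort2)
})

test_that("with zero observer noise the FSS label is the clamped latent level", {
  cohort <- generate_cohort(6, 3, fss_noise_sd = 0, include_eeg = FALSE,
                            seed = 11)
  expect_equal(cohort$fss, pmin(pmax(round(2 * cohort$level) / 2, 0), 4))
})

test_that("EEG recordings round-trip through the CSV interchange format", {
  rec <- generate_eeg(fatigue_profile(level = 1), n_channels = 3,
                      duration = 4, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eeg_csv(rec, path)
  back <- read_eeg_csv(path)
  expect_equal(back$fs, rec$fs, tolerance = 1e-9)
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$data, rec$data, tolerance = 1e-9,
               ignore_attr = TRUE)
})
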