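test_that("default configuration reproduces the DEAP recording geometry", {
  s <- full_subject()
  expect_equal(dim(s$recording$data), c(40, 32, 8064))
  expect_equal(s$recording$sample_rate_hz, 128)
  expect_length(s$recording$channel_names, 32)
  expect_true(all(s$recording$channel_names %in% electrode_grid()$channel))
  expect_true(all(s$ratings$valence >= 1 & s$ratings$valence <= 9))
  expect_true(all(s$ratings$arousal >= 1 & s$ratings$arousal <= 9))
  expect_true(all(s$ratings$latent_valence %in% 0:1))
})

test_that("generation is bit-identical under the same seed and differs under another", {
  a <- generate_subject(subject_profile(2), small_cfg(seed = 11))
  b <- generate_subject(subject_profile(2), small_cfg(seed = 11))
  d <- generate_subject(subject_profile(2), small_cfg(seed = 12))
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$ratings, b$ratings)
  expect_false(identical(a$recording$data, d$recording$data))
})

test_that("frontal beta/gamma power carries the class effect and zero effect removes it", {
  fs <- 128
  frontal <- c("Fp1", "Fp2", "AF3", "AF4", "F3", "F4", "F7", "F8")
  pow_by_class <- function(effect, seed = 40) {
    cfg <- synth_config(n_trials = 40, trial_len_s = 13, seed = seed,
                        effect_size = effect)
    s <- generate_subject(subject_profile(1), cfg)
    rec <- strip_baseline(s$recording)
    chan <- match(frontal, rec$channel_names)
    p <- vapply(seq_len(40), function(tr) {
      x <- rec$data[tr, chan, ]
      band_power(x, "gamma", fs)
    }, numeric(1))
    split(p, s$ratings$latent_valence)
  }
  p0 <- pow_by_class(0)
  expect_gt(t.test(p0[["1"]], p0[["0"]])$p.value, 0.01)
  gaps <- vapply(c(0, 0.5, 1), function(e) {
    p <- pow_by_class(e)
    mean(p[["1"]]) - mean(p[["0"]])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("ratings track the latent class around the threshold of 5", {
  s <- full_subject()
  lab <- binarize_rating(s$ratings$valence)
  expect_gt(mean(lab == s$ratings$latent_valence), 0.9)
})

test_that("cohort draws respect the distortion strength and reproduce under a seed", {
  cfg <- small_cfg(seed = 13)
  co0 <- generate_cohort(3, cfg, distortion_strength = 0)
  grid <- seq(0, 1, length.out = 11)
  for (s in co0)
    expect_equal(s$profile$distortion(grid), grid, tolerance = 1e-12)
  co1a <- generate_cohort(2, cfg, distortion_strength = 1)
  co1b <- generate_cohort(2, cfg, distortion_strength = 1)
  expect_identical(co1a[[2]]$recording$data, co1b[[2]]$recording$data)
  for (s in co1a) {
    expect_true(s$profile$distortion_exponent >= 0.5 - 1e-9)
    expect_true(s$profile$distortion_exponent <= 2 + 1e-9)
    expect_equal(dim(s$recording$data), c(8, 32, 13 * 128))
  }
  expect_error(generate_cohort(0, cfg), "n_subjects")
})

test_that("invalid configurations and profiles are rejected", {
  expect_error(synth_config(trial_len_s = 63.003), "integer")
  expect_error(synth_config(n_channels = 40), "n_channels")
  expect_error(synth_config(noise_sd = 0), "noise_sd")
  expect_error(subject_profile(1, gain = 0), "gain")
  expect_error(subject_profile(1, latency_s = 3), "latency")
  expect_error(subject_profile(1, distortion = function(p) 1 - p),
               "monotone")
  expect_error(subject_profile(1, distortion = function(p) 2 * p),
               "monotone")
})

test_that("subject recordings round-trip through the on-disk container", {
  dir <- withr::local_tempdir()
  s <- small_subject()
  write_subject_data(s$recording, s$ratings, dir)
  back <- read_subject_data(dir, 1)
  expect_identical(back$recording$data, s$recording$data)
  expect_equal(back$ratings, s$ratings)
})
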