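make_rec <- function(data, fs = 128, channels = NULL, id = 1L) {
  structure(list(
    data = data, sample_rate_hz = fs,
    channel_names = channels %||% eegemotion:::DEAP_CHANNELS[seq_len(dim(data)[2])],
    subject_id = id
  ), class = "eeg_recording")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("baseline removal drops exactly the first seconds of every trial", {
  s <- full_subject()
  trimmed <- strip_baseline(s$recording, 3)
  expect_equal(dim(trimmed$data), c(40, 32, 7680))
  expect_identical(trimmed$data[1, 1, ], s$recording$data[1, 1, 385:8064])
  expect_identical(strip_baseline(s$recording, 0), s$recording)
  expect_error(strip_baseline(s$recording, 63), "shorter")
})

test_that("polyphase resampling preserves a tone's frequency", {
  fs <- 512
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  rec <- make_rec(array(x, c(1, 1, length(x))), fs = fs,
                  channels = "Fp1")
  out <- resample_recording(rec, 128)
  expect_equal(out$sample_rate_hz, 128)
  expect_equal(dim(out$data)[3], 512)
  spec <- Mod(fft(out$data[1, 1, ]))[1:256]
  peak_hz <- (which.max(spec[-1])) * 128 / 512   # skip DC
  expect_equal(peak_hz, 10)
  expect_identical(resample_recording(rec, fs), rec)
  expect_error(resample_recording(rec, 1024), "upsampling")
})

test_that("segmentation tiles trials exactly and preserves provenance", {
  s <- full_subject()
  seg <- segment_trials(strip_baseline(s$recording), 0.5)
  expect_equal(dim(seg$data), c(4800, 32, 64))
  expect_equal(length(unique(seg$trial)), 40)
  expect_equal(sum(seg$trial == 1), 120)
  # first segment of trial 2 is the start of trial 2's post-baseline data
  expect_identical(seg$data[121, , 1:64],
                   strip_baseline(s$recording)$data[2, , 1:64])
  expect_error(segment_trials(strip_baseline(s$recording), 0.7),
               "integer|divisible")
  expect_error(segment_trials(strip_baseline(s$recording), 7),
               "divisible")
  tiny <- make_rec(array(rnorm(128), c(1, 1, 128)), channels = "Cz")
  expect_equal(dim(segment_trials(tiny, 0.5)$data)[1], 2)
})

test_that("segment counts are conserved for every window that divides the trial", {
  rec <- strip_baseline(small_subject()$recording)
  for (w in c(0.5, 1, 2)) {
    seg <- segment_trials(rec, w)
    expect_equal(dim(seg$data)[1], 8 * 10 / w)
  }
})

test_that("the band-pass bank isolates tones into their own bands", {
  fs <- 128
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  sine10 <- matrix(sin(2 * pi * 10 * t), nrow = 1)
  out <- bandpass_bank(sine10, sample_rate_hz = fs)
  expect_named(out, c("theta", "alpha", "beta", "gamma"))
  expect_gt(var(out$alpha[1, ]), 100 * var(out$theta[1, ]))
  zero <- matrix(0, 2, 256)
  for (b in bandpass_bank(zero, sample_rate_hz = fs))
    expect_true(all(b == 0))
  # gamma 31-50 Hz is admissible at 128 Hz (Nyquist 64)
  expect_silent(bandpass_bank(sine10, eeg_bands()[4, ], fs))
  bad <- data.frame(name = "bad", low_hz = 40, high_hz = 70)
  expect_error(bandpass_bank(sine10, bad, fs), "Nyquist")
})

test_that("each band captures its own tone's power and rejects the others", {
  fs <- 128
  t <- seq(0, 16 - 1 / fs, by = 1 / fs)
  tones <- list(theta = 5, alpha = 10, beta = 20, gamma = 40)
  x <- matrix(Reduce(`+`, lapply(tones, function(f) sin(2 * pi * f * t))),
              nrow = 1)
  out <- bandpass_bank(x, sample_rate_hz = fs)
  own <- 0.5   # variance of a unit sine
  mid <- 200:(length(t) - 200)
  for (b in names(tones)) {
    pb <- var(out[[b]][1, mid])
    expect_lt(abs(pb - own) / own, 0.05)
    for (other in setdiff(names(tones), b)) {
      xo <- matrix(sin(2 * pi * tones[[other]] * t), nrow = 1)
      po <- var(bandpass_bank(xo, sample_rate_hz = fs)[[b]][1, mid])
      expect_lt(po, 0.01 * own)
    }
  }
})

test_that("rating binarization partitions 1..9 at the threshold", {
  expect_identical(binarize_rating(5), 0L)
  expect_identical(binarize_rating(6), 1L)
  expect_identical(binarize_rating(c(1, 9)), c(0L, 1L))
  expect_identical(binarize_rating(1:9), as.integer(1:9 > 5))
  expect_error(binarize_rating(0), "ratings")
  expect_error(binarize_rating(10), "ratings")
  expect_error(binarize_rating(5, threshold = 0), "threshold")
})
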