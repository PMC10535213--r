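#' Canonical EEG frequency bands
#'
#' The four bands used for emotion-related differential entropy features:
#' theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz, gamma 31-50 Hz.
#'
#' @return data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("theta", "alpha", "beta", "gamma"),
    low_hz = c(4, 8, 14, 31),
    high_hz = c(7, 13, 30, 50)
  )
}

#' Discard the pre-stimulus baseline
#'
#' Removes the first `baseline_s` seconds of every trial (3 s by default,
#' matching the DEAP layout where 8064 samples shrink to 7680).
#'
#' @param rec an `eeg_recording`.
#' @param baseline_s seconds to discard; must be shorter than the trial.
#' @return the trimmed `eeg_recording`.
#' @export
strip_baseline <- function(rec, baseline_s = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  nb <- round(baseline_s * rec$sample_rate_hz)
  ns <- dim(rec$data)[3]
  if (nb < 0 || nb >= ns) stop("baseline_s must be shorter than the trial")
  if (nb == 0) return(rec)
  rec$data <- rec$data[, , (nb + 1):ns, drop = FALSE]
  rec
}

#' Polyphase resampling of a recording
#'
#' Downsamples every trial and channel to `target_hz` with `signal::resample`
#' (polyphase FIR). Requesting a rate above the current one is an error; equal
#' rates return the recording unchanged.
#'
#' @param rec an `eeg_recording`.
#' @param target_hz target sampling rate in Hz.
#' @return the resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_hz = 128) {
  stopifnot(inherits(rec, "eeg_recording"))
  cur <- rec$sample_rate_hz
  if (target_hz > cur) stop("upsampling is not supported (target above current rate)")
  if (target_hz == cur) return(rec)
  g <- gcd_int(round(target_hz), round(cur))
  p <- round(target_hz) / g; q <- round(cur) / g
  d <- dim(rec$data)
  n_out <- floor(d[3] * p / q)
  out <- array(0, dim = c(d[1], d[2], n_out))
  for (tr in seq_len(d[1])) for (ch in seq_len(d[2])) {
    y <- signal::resample(rec$data[tr, ch, ], p, q)
    out[tr, ch, ] <- y[seq_len(n_out)]
  }
  rec$data <- out
  rec$sample_rate_hz <- target_hz
  rec
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Split trials into non-overlapping windows
#'
#' Cuts each trial into consecutive `window_s`-second segments (0.5 s by
#' default). Windows must tile the trial exactly; there is no partial-window
#' salvage, so 40 trials of 60 s yield exactly 4800 segments.
#'
#' @param rec an `eeg_recording` (baseline already stripped).
#' @param window_s window length in seconds.
#' @return an object of class `segment_set`: `data` array
#'   n_segments x channels x window_samples plus `trial`, `segment`,
#'   `subject_id`, `sample_rate_hz`, `channel_names`.
#' @export
segment_trials <- function(rec, window_s = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  wn <- window_s * rec$sample_rate_hz
  if (abs(wn - round(wn)) > 1e-9) stop("window_s must be an integer number of samples")
  wn <- as.integer(round(wn))
  d <- dim(rec$data)
  if (d[3] %% wn != 0)
    stop("trial length is not divisible by the window (no partial segments)")
  k <- d[3] %/% wn
  n_seg <- d[1] * k
  # trial-major ordering, segments consecutive within each trial
  data <- array(0, dim = c(n_seg, d[2], wn))
  for (tr in seq_len(d[1])) {
    x <- rec$data[tr, , , drop = FALSE]  # 1 x ch x samples
    dim(x) <- c(d[2], d[3])
    dim(x) <- c(d[2], wn, k)
    data[(tr - 1) * k + seq_len(k), , ] <- aperm(x, c(3, 1, 2))
  }
  structure(list(
    data = data, trial = rep(seq_len(d[1]), each = k),
    segment = rep(seq_len(k), times = d[1]), subject_id = rec$subject_id,
    sample_rate_hz = rec$sample_rate_hz, channel_names = rec$channel_names
  ), class = "segment_set")
}

#' Zero-phase band-pass filter bank
#'
#' Filters a channels x samples matrix (or the `data` matrix of one segment)
#' through 4th-order Butterworth band-passes applied forward and backward
#' (zero phase), one output per band.
#'
#' @param x numeric matrix, channels x samples.
#' @param bands band definition data frame as from [eeg_bands()].
#' @param sample_rate_hz sampling rate of `x` in Hz.
#' @return named list of filtered matrices, one per band, same shape as `x`.
#' @export
bandpass_bank <- function(x, bands = eeg_bands(), sample_rate_hz = 128) {
  stopifnot(is.matrix(x))
  bank <- butter_bank(bands, sample_rate_hz)
  out <- lapply(bank, function(f) t(filtfilt_mat(f$b, f$a, t(x))))
  names(out) <- bands$name
  out
}

#' Binarize a 1-9 self-assessment rating
#'
#' Ratings at or below the threshold (default 5) map to class 0 (negative /
#' low), ratings above it to class 1 (positive / high).
#'
#' @param rating integer vector of ratings in 1..9.
#' @param threshold decision threshold within `[1, 9]`.
#' @return integer vector of 0/1 labels.
#' @export
binarize_rating <- function(rating, threshold = 5) {
  if (threshold < 1 || threshold > 9) stop("threshold must lie in [1, 9]")
  if (any(rating < 1 | rating > 9)) stop("ratings must lie in [1, 9]")
  as.integer(rating > threshold)
}
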