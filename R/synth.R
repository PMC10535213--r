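#' Configuration for the synthetic EEG generator
#'
#' Defaults reproduce the DEAP recording geometry: 40 trials of 63 s (3 s
#' pre-stimulus baseline + 60 s stimulus) from 32 channels sampled at 128 Hz,
#' i.e. a per-subject array of shape 40 x 32 x 8064.
#'
#' @param n_trials number of trials per subject.
#' @param n_channels number of electrodes; must not exceed the 32-channel
#'   montage in [electrode_grid()].
#' @param sample_rate_hz sampling rate in Hz.
#' @param trial_len_s trial length in seconds, baseline included.
#' @param baseline_s pre-stimulus baseline in seconds.
#' @param effect_size relative modulation of frontal beta/gamma band amplitude
#'   by the latent valence class (`>= 0`, 0 = no class signal).
#' @param noise_sd standard deviation of the pink background noise; band
#'   components have half this amplitude.
#' @param seed integer seed controlling every draw of the generator.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_trials = 40, n_channels = 32, sample_rate_hz = 128,
                         trial_len_s = 63, baseline_s = 3, effect_size = 1,
                         noise_sd = 1, seed = 1) {
  ns <- trial_len_s * sample_rate_hz
  if (abs(ns - round(ns)) > 1e-9)
    stop("trial_len_s * sample_rate_hz must be an integer number of samples")
  if (n_channels < 1 || n_channels > length(DEAP_CHANNELS))
    stop("n_channels must be between 1 and ", length(DEAP_CHANNELS))
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (baseline_s < 0 || baseline_s >= trial_len_s)
    stop("baseline_s must lie in [0, trial_len_s)")
  structure(list(
    n_trials = as.integer(n_trials), n_channels = as.integer(n_channels),
    sample_rate_hz = sample_rate_hz, trial_len_s = trial_len_s,
    baseline_s = baseline_s, effect_size = effect_size, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Per-subject response profile
#'
#' Encodes the individual differences the calibration stage must undo: an
#' amplitude gain, a delayed onset of the emotional band-power effect, a bias
#' of the self-assessment rating, and a monotone distortion of the ideal class
#' probability.
#'
#' @param subject_id integer identifier.
#' @param gain positive amplitude multiplier applied to the whole recording.
#' @param latency_s onset delay (seconds, within `[0, 2]`) of the class effect
#'   after the stimulus starts.
#' @param intensity_bias additive shift of the latent 1-9 rating.
#' @param distortion monotone nondecreasing function from `[0,1]` to `[0,1]`
#'   applied to the ideal class probability; defaults to the identity. Power
#'   laws `p^a` are the family drawn by [generate_cohort()].
#' @param distortion_exponent optional exponent `a`; when given, `distortion`
#'   is set to `p^a` and the exponent is retained for printing.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, gain = 1, latency_s = 0,
                            intensity_bias = 0, distortion = identity,
                            distortion_exponent = NULL) {
  if (gain <= 0) stop("gain must be > 0")
  if (latency_s < 0 || latency_s > 2) stop("latency_s must lie in [0, 2]")
  if (!is.null(distortion_exponent)) {
    a <- distortion_exponent
    if (a <= 0) stop("distortion_exponent must be > 0")
    distortion <- local({ a <- a; function(p) p^a })
  }
  grid <- seq(0, 1, length.out = 101)
  dv <- distortion(grid)
  if (any(!is.finite(dv)) || any(dv < -1e-9) || any(dv > 1 + 1e-9) ||
      any(diff(dv) < -1e-9))
    stop("distortion must be monotone nondecreasing from [0,1] into [0,1]")
  structure(list(
    subject_id = as.integer(subject_id), gain = gain, latency_s = latency_s,
    intensity_bias = intensity_bias, distortion = distortion,
    distortion_exponent = distortion_exponent
  ), class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "subject profile %d: gain %.3f, latency %.2f s, intensity bias %+.2f, distortion %s\n",
    x$subject_id, x$gain, x$latency_s, x$intensity_bias,
    if (is.null(x$distortion_exponent)) "custom"
    else sprintf("p^%.3f", x$distortion_exponent)))
  invisible(x)
}

# Butterworth coefficient bank for the four canonical bands.
butter_bank <- function(bands, sample_rate_hz, order = 4) {
  nyq <- sample_rate_hz / 2
  lapply(seq_len(nrow(bands)), function(i) {
    lo <- bands$low_hz[i]; hi <- bands$high_hz[i]
    if (lo <= 0 || hi <= lo) stop("invalid band edges")
    if (hi >= nyq) stop("band '", bands$name[i], "' exceeds the Nyquist rate")
    bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
    list(b = as.numeric(bf$b), a = as.numeric(bf$a), name = bands$name[i])
  })
}

# Pink (1/f) background noise, one column per channel; unit SD per column.
pink_noise <- function(n, n_channels) {
  w <- matrix(rnorm(n * n_channels), n, n_channels)
  W <- mvfft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)
  sc <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(mvfft(W * sc, inverse = TRUE)) / n
  scale(x, center = FALSE, scale = apply(x, 2, sd))
}

#' Generate one synthetic subject
#'
#' Each trial is pink background noise plus four band-limited noise components
#' (theta/alpha/beta/gamma, synthesised by zero-phase Butterworth filtering of
#' white noise). The beta and gamma components in the frontal channels (Fp1,
#' Fp2, AF3, AF4, F3, F4, F7, F8) are scaled by
#' `1 + effect_size * (2 * latent_valence - 1)`, ramping on only after the
#' subject's `latency_s` into the post-baseline window. The whole trial is
#' multiplied by the subject's gain. Self-assessment ratings are drawn around
#' the class centres `5 +/- (2 + effect_size)` with the subject's intensity
#' bias and N(0, 0.5) noise, clamped to 1..9.
#'
#' @param profile a [subject_profile()].
#' @param cfg a [synth_config()].
#' @return a list with components `recording` (class `eeg_recording`: `data`
#'   array trials x channels x samples, `sample_rate_hz`, `channel_names`,
#'   `subject_id`) and `ratings` (data frame with trial, valence, arousal and
#'   the latent binary classes).
#' @export
generate_subject <- function(profile, cfg) {
  stopifnot(inherits(profile, "subject_profile"), inherits(cfg, "synth_config"))
  n <- as.integer(round(cfg$trial_len_s * cfg$sample_rate_hz))
  nc <- cfg$n_channels
  channels <- DEAP_CHANNELS[seq_len(nc)]
  bank <- butter_bank(eeg_bands(), cfg$sample_rate_hz)
  frontal <- which(channels %in% FRONTAL_CHANNELS)
  effect_bands <- which(eeg_bands()$name %in% c("beta", "gamma"))

  # class-effect gate: 0 through baseline + latency, 0.25 s linear ramp, then 1
  tt <- (seq_len(n) - 1) / cfg$sample_rate_hz
  onset <- cfg$baseline_s + profile$latency_s
  gate <- pmin(pmax((tt - onset) / 0.25, 0), 1)

  with_seed(derive_seed(cfg$seed, profile$subject_id), {
    lv <- sample(rep(0:1, length.out = cfg$n_trials))
    la <- sample(rep(0:1, length.out = cfg$n_trials))
    data <- array(0, dim = c(cfg$n_trials, nc, n))
    for (tr in seq_len(cfg$n_trials)) {
      x <- cfg$noise_sd * pink_noise(n, nc)
      fac <- 1 + cfg$effect_size * (2 * lv[tr] - 1)
      for (bi in seq_along(bank)) {
        w <- matrix(rnorm(n * nc), n, nc)
        comp <- filtfilt_mat(bank[[bi]]$b, bank[[bi]]$a, w)
        comp <- 0.5 * cfg$noise_sd *
          scale(comp, center = FALSE, scale = apply(comp, 2, sd))
        if (bi %in% effect_bands && length(frontal) && cfg$effect_size > 0)
          comp[, frontal] <- comp[, frontal] * (1 + (fac - 1) * gate)
        x <- x + comp
      }
      data[tr, , ] <- t(profile$gain * x)
    }
    shift <- 2 + cfg$effect_size
    val <- pmin(pmax(round(5 + (2 * lv - 1) * shift + profile$intensity_bias +
                             rnorm(cfg$n_trials, 0, 0.5)), 1), 9)
    aro <- pmin(pmax(round(5 + (2 * la - 1) * shift + profile$intensity_bias +
                             rnorm(cfg$n_trials, 0, 0.5)), 1), 9)
    rec <- structure(list(
      data = data, sample_rate_hz = cfg$sample_rate_hz,
      channel_names = channels, subject_id = profile$subject_id
    ), class = "eeg_recording")
    ratings <- data.frame(
      trial = seq_len(cfg$n_trials), valence = as.integer(val),
      arousal = as.integer(aro), latent_valence = lv, latent_arousal = la
    )
    list(recording = rec, ratings = ratings)
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("eeg_recording: subject %d, %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$sample_rate_hz))
  invisible(x)
}

#' Draw a reproducible cohort of synthetic subjects
#'
#' Subject profiles are drawn from the cohort distributions: gain lognormal
#' with log-sd 0.1, latency uniform on 0-1 s, intensity bias uniform on
#' -1..1, and a power-law score distortion `p^a` with `a` log-uniform on
#' `[1/(1+distortion_strength), 1+distortion_strength]` (identity when the
#' strength is 0).
#'
#' @param n_subjects number of subjects (`>= 1`).
#' @param cfg a [synth_config()]; its seed controls both the profile draws and
#'   every recording.
#' @param distortion_strength nonnegative scalar controlling the spread of the
#'   power-law score distortions.
#' @return a list of class `eeg_cohort`; one element per subject with
#'   components `recording`, `ratings`, `profile`.
#' @export
generate_cohort <- function(n_subjects, cfg, distortion_strength = 0) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (distortion_strength < 0) stop("distortion_strength must be >= 0")
  profiles <- draw_profiles(n_subjects, cfg, distortion_strength)
  out <- lapply(profiles, function(pr) {
    c(generate_subject(pr, cfg), list(profile = pr))
  })
  class(out) <- "eeg_cohort"
  out
}

# Profile draws shared by generate_cohort() and cohort_features().
draw_profiles <- function(n_subjects, cfg, distortion_strength) {
  with_seed(derive_seed(cfg$seed, 777001), {
    gains <- exp(rnorm(n_subjects, 0, 0.1))
    lats <- runif(n_subjects, 0, 1)
    bias <- runif(n_subjects, -1, 1)
    la <- log(1 + distortion_strength)
    expo <- exp(runif(n_subjects, -la, la))
    lapply(seq_len(n_subjects), function(i)
      subject_profile(i, gain = gains[i], latency_s = lats[i],
                      intensity_bias = bias[i], distortion_exponent = expo[i]))
  })
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("eeg_cohort of %d subjects\n", length(x)))
  for (s in x) print(s$profile)
  invisible(x)
}

#' Write / read one subject's recording and ratings
#'
#' The recording (data array plus sample rate and channel names) is stored as
#' an RDS container `subject_<id>.rds`; ratings go to a companion CSV
#' `subject_<id>_ratings.csv` with columns trial, valence, arousal,
#' latent_valence, latent_arousal.
#'
#' @param recording an `eeg_recording`.
#' @param ratings the matching ratings data frame.
#' @param dir output directory (created if missing).
#' @return (invisibly) the paths written.
#' @export
write_subject_data <- function(recording, ratings, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- recording$subject_id
  rds <- file.path(dir, sprintf("subject_%02d.rds", id))
  csv <- file.path(dir, sprintf("subject_%02d_ratings.csv", id))
  saveRDS(recording, rds)
  write.csv(ratings, csv, row.names = FALSE)
  invisible(c(rds, csv))
}

#' @rdname write_subject_data
#' @param subject_id id of the subject to read back.
#' @return `read_subject_data`: a list with `recording` and `ratings`.
#' @export
read_subject_data <- function(dir, subject_id) {
  rec <- readRDS(file.path(dir, sprintf("subject_%02d.rds", subject_id)))
  ratings <- read.csv(file.path(dir, sprintf("subject_%02d_ratings.csv", subject_id)))
  list(recording = rec, ratings = ratings)
}
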