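# Shared fixtures, built once per test session and memoised.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# one full DEAP-geometry subject (40 x 32 x 8064), moderate class effect
full_subject <- function() memo("full_subject", {
  generate_subject(subject_profile(1),
                   synth_config(seed = 300, effect_size = 1))
})

full_features <- function() memo("full_features", {
  s <- full_subject()
  featurize(strip_baseline(s$recording), s$ratings)
})

# small, fast geometry: 8 trials of 13 s (3 s baseline + 10 s)
small_cfg <- function(seed = 7, n_trials = 8, ...) {
  synth_config(n_trials = n_trials, trial_len_s = 13, seed = seed, ...)
}

small_subject <- function() memo("small_subject", {
  generate_subject(subject_profile(1), small_cfg())
})

# a small trained classifier for structural tests
tiny_net_config <- function() net_config(conv_channels = c(4, 6, 6, 4),
                                         lstm_hidden = 8, batch_size = 16)

tiny_trained <- function() memo("tiny_trained", {
  s <- small_subject()
  ft <- featurize(strip_baseline(s$recording), s$ratings)
  batch <- make_sequences(ft, seq_len = 5)
  net <- emotion_net(batch, tiny_net_config(), epochs = 3, lr = 1e-3,
                     seed = 21)
  list(net = net, batch = batch, ft = ft)
})

# exhaustive isotonic oracle: all contiguous block partitions, weighted block
# means, admissible iff the means are nondecreasing; minimal weighted SSE
oracle_isotonic <- function(y, w) {
  m <- length(y)
  if (m == 1) return(list(fit = sum(w * y) / sum(w), sse = 0))
  best <- NULL; best_sse <- Inf
  for (mask in 0:(2^(m - 1) - 1)) {
    cut <- which(bitwAnd(mask, 2^(0:(m - 2))) > 0)
    starts <- c(1, cut + 1); ends <- c(cut, m)
    vals <- numeric(m); means <- numeric(length(starts)); ok <- TRUE
    for (b in seq_along(starts)) {
      idx <- starts[b]:ends[b]
      means[b] <- sum(w[idx] * y[idx]) / sum(w[idx])
      vals[idx] <- means[b]
    }
    if (any(diff(means) < -1e-12)) ok <- FALSE
    if (ok) {
      sse <- sum(w * (y - vals)^2)
      if (sse < best_sse - 1e-15) { best_sse <- sse; best <- vals }
    }
  }
  list(fit = best, sse = best_sse)
}

# band power (variance) of a filtered recording trial in one band
band_power <- function(x, band, fs) {
  f <- bandpass_bank(x, eeg_bands()[eeg_bands()$name == band, ], fs)[[1]]
  mean(apply(f, 1, var))
}
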