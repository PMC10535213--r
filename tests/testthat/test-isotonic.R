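test_that("pair-adjacent violators reproduces the textbook cases", {
  f1 <- pav_fit(c(0.2, 0.8), c(0, 1))
  expect_equal(f1$fitted, c(0, 1))
  f2 <- pav_fit(c(0.2, 0.8), c(1, 0))
  expect_equal(f2$fitted, c(0.5, 0.5))
  f3 <- pav_fit(c(0.1, 0.4, 0.6, 0.9), c(1, 0, 1, 0))
  expect_equal(f3$fitted, rep(0.5, 4))
  expect_error(pav_fit(numeric(0), numeric(0)), "empty")
  expect_error(pav_fit(c(0.1, 0.2), c(0, 1), w = c(1, 0)), "positive")
  expect_error(pav_fit(0.1, c(0, 1)), "length")
})

test_that("PAV matches the exhaustive block-partition oracle on random instances", {
  set.seed(77)
  for (i in 1:200) {
    m <- sample(1:10, 1)
    f <- sort(runif(m)) + seq_len(m) * 1e-6    # distinct scores
    y <- rbinom(m, 1, 0.5)
    w <- runif(m, 0.2, 3)
    fit <- pav_fit(f, y, w)
    orc <- oracle_isotonic(y, w)
    expect_equal(fit$fitted, orc$fit, tolerance = 1e-9)
    expect_equal(sum(w * (y - fit$fitted)^2), orc$sse, tolerance = 1e-9)
    # monotone fitted values, weighted-mean conservation
    expect_true(all(diff(fit$fit) >= -1e-12))
    expect_equal(sum(w * fit$fitted), sum(w * y), tolerance = 1e-9)
  }
})

test_that("PAV agrees with stats::isoreg under unit weights", {
  set.seed(78)
  for (i in 1:50) {
    m <- sample(2:30, 1)
    f <- sort(runif(m)) + seq_len(m) * 1e-7
    y <- runif(m)
    fit <- pav_fit(f, y)
    ref <- isoreg(f, y)
    expect_equal(fit$fitted, ref$yf, tolerance = 1e-9)
  }
})

test_that("an already-monotone response is returned exactly (idempotence)", {
  y <- c(0, 0, 0.25, 0.5, 0.5, 1)
  fit <- pav_fit(seq_along(y) / 10, y)
  expect_identical(fit$fitted, y)
  again <- pav_fit(seq_along(y) / 10, fit$fitted)
  expect_identical(again$fitted, y)
})

test_that("tied scores are pre-pooled by weighted mean", {
  fit <- pav_fit(c(0.5, 0.5, 0.9), c(0, 1, 1), w = c(1, 3, 1))
  expect_equal(fit$x, c(0.5, 0.9))
  expect_equal(fit$fit[1], 0.75)
  expect_equal(fit$fitted[1], fit$fitted[2])
})

test_that("step evaluation clamps outside the fitted range and keeps rank order", {
  fit <- pav_fit(c(0.2, 0.8), c(0, 1))
  expect_equal(predict(fit, 0.1), 0)
  expect_equal(predict(fit, 0.9), 1)
  const <- pav_fit(c(0.3, 0.7), c(1, 0))
  expect_equal(predict(const, c(0, 0.5, 1)), rep(0.5, 3))
  set.seed(80)
  f <- runif(40); y <- rbinom(40, 1, f)
  fit2 <- pav_fit(f, y)
  xs <- sort(runif(100))
  expect_true(all(diff(predict(fit2, xs)) >= -1e-12))
})

test_that("calibration recovers accuracy lost to a monotone score distortion", {
  res <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 240
    p <- runif(n, 0.02, 0.98)
    y <- rbinom(n, 1, p)
    pd <- p^3
    cal <- calibrate_subject(cbind(1 - pd, pd), cbind(1 - y, y),
                             calib_fraction = 0.5, seed = s)
    c(cal$accuracy_raw, cal$accuracy_calibrated)
  }, numeric(2))
  expect_gte(sum(res[2, ] >= res[1, ]), 8)
  expect_gt(mean(res[2, ] - res[1, ]), 0.03)
})

test_that("well-calibrated scores are left essentially unchanged", {
  set.seed(91)
  n <- 240
  p <- runif(n, 0.02, 0.98)
  y <- rbinom(n, 1, p)
  cal <- calibrate_subject(cbind(1 - p, p), cbind(1 - y, y),
                           calib_fraction = 0.5, seed = 91)
  expect_lt(abs(cal$accuracy_calibrated - cal$accuracy_raw), 0.02 + 1e-9)
})

test_that("a single-class calibration split falls back to identity with a warning", {
  scores <- cbind(seq(0.1, 0.9, length.out = 12),
                  1 - seq(0.1, 0.9, length.out = 12))
  labels <- cbind(rep(1, 12), rep(0, 12))   # one class only
  expect_warning(cal <- calibrate_subject(scores, labels, seed = 1),
                 "identity")
  expect_true(cal$fallback)
  expect_equal(cal$calibrated_eval, cal$scores_eval)
  expect_error(calibrate_subject(scores[1:4, ], labels[1:4, ]), "fewer")
})

test_that("observer residuals shrink when a systematic shift is calibrated away", {
  set.seed(3)
  n <- 200
  p <- runif(n, 0.05, 0.8); y <- rbinom(n, 1, p)
  labels <- cbind(1 - y, y)
  before <- cbind(1 - p, p) + 0.2
  fits <- lapply(1:2, function(u) pav_fit(before[, u], labels[, u]))
  after <- vapply(1:2, function(u) predict(fits[[u]], before[, u]),
                  numeric(n))
  r <- observer_residuals(before, after, labels)
  expect_lt(abs(r$mean_residual_after), abs(r$mean_residual_before))
  # perfect predictions give zero residuals throughout
  r0 <- observer_residuals(labels, labels, labels)
  expect_equal(r0$mean_residual_before, 0)
  expect_equal(r0$mean_residual_after, 0)
  # one row per subject
  subj <- rep(1:4, each = 50)
  r4 <- observer_residuals(before, after, labels, subject = subj)
  expect_equal(nrow(r4), 4)
  expect_error(observer_residuals(before[1:10, ], after, labels), "misaligned")
})
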