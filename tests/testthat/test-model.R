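test_that("the adaptive attention kernel size follows the channel count", {
  expect_equal(eca_kernel_size(32), 3L)
  expect_equal(eca_kernel_size(256), 5L)
  expect_equal(eca_kernel_size(2), 1L)
  k <- eca_kernel_size(1:512)
  expect_true(all(k %% 2 == 1))
  expect_true(all(k >= 1))
  expect_true(all(diff(k) >= 0))
  expect_error(eca_kernel_size(0), "C")
})

test_that("channel attention gates lie in (0,1) and preserve shape", {
  set.seed(4)
  x <- array(rnorm(2 * 64 * 9 * 9), c(2, 64, 9, 9))
  out <- eca_forward(x)
  expect_equal(dim(out$out), dim(x))
  expect_true(all(out$weights > 0 & out$weights < 1))
  z <- eca_forward(array(0, c(1, 8, 4, 4)))
  expect_true(all(z$out == 0))
  expect_true(all(is.finite(z$weights)))
})

test_that("analytic gradients match finite differences through every layer", {
  set.seed(7)
  cfg <- net_config(conv_channels = c(3, 4, 4, 3), lstm_hidden = 5,
                    seq_len = 2, dropout = 0)
  n <- 3; T <- 2
  X <- array(rnorm(n * T * 4 * 9 * 9), c(n, T, 4, 9, 9))
  Y <- cbind(c(1, 0, 1), c(0, 1, 0))
  ini <- eegemotion:::init_params(cfg, 4, seed = 3)
  lossfun <- function(params) {
    fw <- eegemotion:::net_forward(params, ini$state, cfg, X,
                                   training = TRUE, collect = TRUE)
    lg <- eegemotion:::net_loss_grad(fw$scores, Y, cfg$loss)
    list(loss = lg$loss, fw = fw, lg = lg)
  }
  r <- lossfun(ini$params)
  grads <- eegemotion:::net_backward(ini$params, cfg, r$fw$caches,
                                     r$lg$dlogits)
  eps <- 1e-6
  worst <- 0
  for (nm in names(ini$params)) {
    set.seed(nchar(nm))
    for (j in sample(length(ini$params[[nm]]),
                     min(4, length(ini$params[[nm]])))) {
      p2 <- ini$params
      p2[[nm]][j] <- p2[[nm]][j] + eps; l1 <- lossfun(p2)$loss
      p2[[nm]][j] <- p2[[nm]][j] - 2 * eps; l0 <- lossfun(p2)$loss
      num <- (l1 - l0) / (2 * eps)
      ana <- grads[[nm]][j]
      worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("the end-to-end shape contract holds, including one-step sequences", {
  tr <- tiny_trained()
  sc <- predict(tr$net, tr$batch)
  expect_equal(dim(sc), c(length(tr$batch$label), 2))
  expect_true(all(sc > 0 & sc < 1))
  # seq_len = 1 degenerates gracefully
  b1 <- make_sequences(tr$ft, seq_len = 1)
  n1 <- emotion_net(subset_sequences(b1, 1:20), tiny_net_config(),
                    epochs = 1, seed = 5)
  s1 <- predict(n1, subset_sequences(b1, 1:4))
  expect_equal(dim(s1), c(4, 2))
})

test_that("evaluation mode is deterministic and batch-size independent", {
  tr <- tiny_trained()
  s1 <- predict(tr$net, tr$batch)
  s2 <- predict(tr$net, tr$batch)
  expect_identical(s1, s2)
  one <- predict(tr$net, tr$batch$inputs[5, , , , , drop = FALSE])
  expect_equal(unname(s1[5, ]), unname(one[1, ]), tolerance = 1e-12)
  enc <- cnn_encode(tr$net, tr$batch)
  expect_equal(dim(enc)[1:2], c(length(tr$batch$label), 5))
  enc_one <- cnn_encode(tr$net, tr$batch$inputs[5, , , , , drop = FALSE])
  expect_equal(enc[5, , ], enc_one[1, , ], tolerance = 1e-12)
})

test_that("both recurrent directions read the sequence", {
  tr <- tiny_trained()
  X <- tr$batch$inputs[1:6, , , , , drop = FALSE]
  Xrev <- X[, 5:1, , , , drop = FALSE]
  expect_false(isTRUE(all.equal(predict(tr$net, X), predict(tr$net, Xrev))))
})

test_that("loss and decision primitives follow their definitions", {
  expect_equal(mse_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1)), 0)
  expect_equal(mse_loss(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1)), 0.25)
  set.seed(8)
  p <- matrix(runif(20), 10); y <- matrix(rbinom(20, 1, 0.5), 10)
  expect_gte(mse_loss(p, y), 0)
  expect_error(mse_loss(matrix(0, 2, 2), matrix(0, 2, 1)), "shape")
  expect_equal(predict_class(matrix(c(0.9, 0.1), 1)), 0L)
  expect_equal(predict_class(matrix(c(0.5, 0.5), 1)), 0L)
  expect_equal(predict_class(matrix(c(0.2, 0.8), 1)), 1L)
})

test_that("training is seeded-deterministic and checkpoints round-trip", {
  tr <- tiny_trained()
  s <- small_subject()
  batch <- subset_sequences(tr$batch, 1:12)
  n1 <- emotion_net(batch, tiny_net_config(), epochs = 2, seed = 33)
  n2 <- emotion_net(batch, tiny_net_config(), epochs = 2, seed = 33)
  expect_identical(n1$params, n2$params)
  expect_identical(n1$history, n2$history)
  path <- file.path(withr::local_tempdir(), "net.rds")
  save_model(n1, path)
  expect_true(file.exists(sub("rds$", "json", path)))
  n3 <- load_model(path)
  expect_identical(predict(n1, batch), predict(n3, batch))
})

test_that("the loss decreases over training and the fit can overfit a small set", {
  cfgS <- synth_config(n_trials = 40, trial_len_s = 13, effect_size = 2,
                       seed = 17)
  sub <- generate_subject(subject_profile(1), cfgS)
  ft <- featurize(strip_baseline(sub$recording), sub$ratings)
  batch <- subsample_sequences(make_sequences(ft), 64, seed = 9)
  cfg <- net_config(conv_channels = c(8, 16, 16, 8), batch_size = 64)
  net <- emotion_net(batch, cfg, epochs = 100, lr = 0.001, seed = 11)
  expect_lt(tail(net$history$loss, 1), net$history$loss[1])
  acc <- mean(predict(net, batch, type = "class") == batch$label)
  expect_gte(acc, 0.95)
})
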