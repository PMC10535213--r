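# ---- parameter initialisation ----------------------------------------------

init_params <- function(cfg, in_channels = 4, seed = 1) {
  ch <- c(in_channels, cfg$conv_channels)
  K <- cfg$kernel^2
  H <- cfg$lstm_hidden
  D <- 16L * cfg$conv_channels[4]     # 4x4 pooled plane, flattened
  with_seed(seed, {
    p <- list()
    st <- list()
    for (l in 1:4) {
      cin <- ch[l]; cout <- ch[l + 1]
      p[[paste0("c", l, ".W")]] <-
        matrix(rnorm(cin * cout * K, 0, sqrt(2 / (K * cin))), K * cin, cout)
      p[[paste0("c", l, ".g")]] <- rep(1, cout)
      p[[paste0("c", l, ".b")]] <- rep(0, cout)
      p[[paste0("c", l, ".e")]] <-
        rnorm(eca_kernel_size(cout, cfg$eca_b, cfg$eca_gamma), 0, 0.1)
      st[[paste0("c", l)]] <- list(rm = rep(0, cout), rv = rep(1, cout))
    }
    s <- 1 / sqrt(H)
    dirs <- if (cfg$bidirectional) c("f", "r") else "f"
    for (d in dirs) {
      p[[paste0("lstm.Wx.", d)]] <- matrix(runif(D * 4 * H, -s, s), D, 4 * H)
      p[[paste0("lstm.Wh.", d)]] <- matrix(runif(H * 4 * H * 1, -s, s), H, 4 * H)
      b <- rep(0, 4 * H); b[H + seq_len(H)] <- 1    # forget-gate bias
      p[[paste0("lstm.b.", d)]] <- b
    }
    fan <- H * length(dirs)
    p[["out.W"]] <- matrix(rnorm(fan * cfg$out_units, 0, sqrt(1 / fan)),
                           fan, cfg$out_units)
    p[["out.b"]] <- rep(0, cfg$out_units)
    list(params = p, state = st)
  })
}

# Recompute exact batch-norm statistics over the whole training set, layer by
# layer: block l's input is forwarded in eval mode through the already
# finalised blocks < l, so the stored moments are the true activation moments
# of the final weights rather than a momentum-lagged running estimate.
finalize_bn <- function(params, state, cfg, X, chunk = 256) {
  n <- dim(X)[1]
  starts <- seq(1, n, by = chunk)
  for (l in 1:4) {
    s1 <- NULL; s2 <- NULL; rows <- 0
    for (st in starts) {
      idx <- st:min(st + chunk - 1, n)
      Xb <- X[idx, , , , , drop = FALSE]
      N <- length(idx) * dim(X)[2]
      g <- gathers_cached(N, cfg$kernel)
      F <- batch_to_pixmat(Xb)
      for (ll in seq_len(l)) {
        F <- conv_fwd(F, params[[paste0("c", ll, ".W")]], g)$Y
        if (ll == l) break
        bn <- bn_fwd(F, params[[paste0("c", ll, ".g")]],
                     params[[paste0("c", ll, ".b")]],
                     state[[paste0("c", ll)]], training = FALSE)
        F <- eca_fwd(bn$Y, params[[paste0("c", ll, ".e")]], N, g$P)$Y
        F <- pmax(F, 0) + cfg$leaky_slope * pmin(F, 0)
      }
      s1 <- (s1 %||% 0) + colSums(F)
      s2 <- (s2 %||% 0) + colSums(F^2)
      rows <- rows + nrow(F)
    }
    m <- s1 / rows
    v <- (s2 - rows * m^2) / max(rows - 1, 1)
    state[[paste0("c", l)]] <- list(rm = m, rv = v)
  }
  state
}

# batch array (n, T, C, 9, 9) -> pixel-major matrix ((n*T*81) x C)
batch_to_pixmat <- function(X) {
  d <- dim(X)
  A <- aperm(X, c(4, 5, 2, 1, 3))
  dim(A) <- c(d[4] * d[5] * d[2] * d[1], d[3])
  A
}

# ---- full network forward / backward ---------------------------------------

net_forward <- function(params, state, cfg, X, training = FALSE,
                        collect = FALSE) {
  d <- dim(X)
  n <- d[1]; T <- d[2]
  N <- n * T
  g <- gathers_cached(N, cfg$kernel)
  F <- batch_to_pixmat(X)
  caches <- if (collect) list(g = g, n = n, T = T, F0 = F) else NULL
  for (l in 1:4) {
    cv <- conv_fwd(F, params[[paste0("c", l, ".W")]], g)
    F <- cv$Y
    bn <- bn_fwd(F, params[[paste0("c", l, ".g")]],
                 params[[paste0("c", l, ".b")]],
                 state[[paste0("c", l)]], training)
    state[[paste0("c", l)]] <- bn$state
    ec <- eca_fwd(bn$Y, params[[paste0("c", l, ".e")]], N, g$P)
    F <- ec$Y
    mask <- NULL
    if (training && cfg$dropout > 0) {
      mask <- matrix((runif(length(F)) >= cfg$dropout) / (1 - cfg$dropout),
                     nrow(F), ncol(F))
      F <- F * mask
    }
    pre <- F
    pos <- F > 0
    F <- F * (pos + cfg$leaky_slope * (1 - pos))
    if (collect)
      caches[[paste0("c", l)]] <- list(X2 = cv$X2, bn = bn, bnY = bn$Y,
                                       ec = ec, mask = mask, pre = pre)
  }
  pl <- pool_fwd(F, g)
  V <- flat_fwd(pl$M, N, g$Po)
  H <- cfg$lstm_hidden
  fwd <- lstm_fwd(V, n, T, params[["lstm.Wx.f"]], params[["lstm.Wh.f"]],
                  params[["lstm.b.f"]], reverse = FALSE)
  if (cfg$bidirectional) {
    rev <- lstm_fwd(V, n, T, params[["lstm.Wx.r"]], params[["lstm.Wh.r"]],
                    params[["lstm.b.r"]], reverse = TRUE)
    O <- cbind(fwd$h_final, rev$h_final)
  } else {
    rev <- NULL
    O <- fwd$h_final
  }
  logits <- O %*% params[["out.W"]] +
    matrix(params[["out.b"]], n, cfg$out_units, byrow = TRUE)
  scores <- sigm(logits)
  if (collect) {
    caches$Flast <- F
    caches$pl <- pl; caches$V <- V; caches$fwd <- fwd; caches$rev <- rev
    caches$O <- O; caches$scores <- scores
  }
  list(scores = scores, state = state, caches = caches)
}

net_backward <- function(params, cfg, caches, dlogits) {
  g <- caches$g
  n <- caches$n; T <- caches$T
  N <- n * T
  grads <- list()
  grads[["out.W"]] <- crossprod(caches$O, dlogits)
  grads[["out.b"]] <- colSums(dlogits)
  dO <- dlogits %*% t(params[["out.W"]])
  H <- cfg$lstm_hidden
  D <- ncol(caches$V)
  bf <- lstm_bwd(dO[, seq_len(H), drop = FALSE], caches$fwd, n, T, D,
                 params[["lstm.Wx.f"]], params[["lstm.Wh.f"]])
  grads[["lstm.Wx.f"]] <- bf$dWx
  grads[["lstm.Wh.f"]] <- bf$dWh
  grads[["lstm.b.f"]] <- bf$db
  dV <- bf$dV
  if (cfg$bidirectional) {
    br <- lstm_bwd(dO[, H + seq_len(H), drop = FALSE], caches$rev, n, T, D,
                   params[["lstm.Wx.r"]], params[["lstm.Wh.r"]])
    grads[["lstm.Wx.r"]] <- br$dWx
    grads[["lstm.Wh.r"]] <- br$dWh
    grads[["lstm.b.r"]] <- br$db
    dV <- dV + br$dV
  }
  C4 <- cfg$conv_channels[4]
  dM <- flat_bwd(dV, N, g$Po, C4)
  dF <- pool_bwd(dM, caches$pl$K, g, N * g$P, C4)
  for (l in 4:1) {
    ca <- caches[[paste0("c", l)]]
    pos <- ca$pre > 0
    dF <- dF * (pos + cfg$leaky_slope * (1 - pos))
    if (!is.null(ca$mask)) dF <- dF * ca$mask
    eb <- eca_bwd(dF, ca$bnY, ca$ec, params[[paste0("c", l, ".e")]], N, g$P)
    grads[[paste0("c", l, ".e")]] <- eb$dw
    bb <- bn_bwd(eb$dX, ca$bn, params[[paste0("c", l, ".g")]])
    grads[[paste0("c", l, ".g")]] <- bb$dg
    grads[[paste0("c", l, ".b")]] <- bb$db
    cin <- ncol(ca$X2) %/% g$K
    cb <- conv_bwd(ca$X2, bb$dX, params[[paste0("c", l, ".W")]], g, cin)
    grads[[paste0("c", l, ".W")]] <- cb$dW
    dF <- cb$dX
  }
  grads
}

net_loss_grad <- function(scores, labels, loss) {
  m <- length(scores)
  if (loss == "mse") {
    L <- mean((scores - labels)^2)
    dlogits <- 2 * (scores - labels) * scores * (1 - scores) / m
  } else {
    eps <- 1e-12
    L <- -mean(labels * log(scores + eps) + (1 - labels) * log(1 - scores + eps))
    dlogits <- (scores - labels) / m
  }
  list(loss = L, dlogits = dlogits)
}

# ---- losses and decisions ---------------------------------------------------

#' Mean squared error between sigmoid scores and one-hot labels
#'
#' `L = mean((p - y)^2)`, averaged over every item and output unit.
#'
#' @param scores numeric matrix of predicted probabilities.
#' @param labels 0/1 matrix of the same shape.
#' @return scalar loss.
#' @export
mse_loss <- function(scores, labels) {
  if (!identical(dim(as.matrix(scores)), dim(as.matrix(labels))))
    stop("scores and labels must have the same shape")
  mean((as.matrix(scores) - as.matrix(labels))^2)
}

#' Class decision from sigmoid scores
#'
#' Two-unit scores decide by argmax; a single unit thresholds at 0.5. Ties
#' break toward class 0.
#'
#' @param scores matrix of scores (n x 2 or n x 1), or a vector of
#'   single-unit scores.
#' @return integer vector of 0/1 predicted classes.
#' @export
predict_class <- function(scores) {
  s <- as.matrix(scores)
  if (ncol(s) == 2) as.integer(s[, 2] > s[, 1]) else as.integer(s[, 1] > 0.5)
}

# ---- Adam -------------------------------------------------------------------

adam_step <- function(params, grads, opt, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * gr
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# ---- the fitter -------------------------------------------------------------

#' Fit the spatio-temporal emotion classifier
#'
#' Trains the convolutional channel-attention network with a bidirectional
#' LSTM head on a [make_sequences()] batch: four conv blocks (conv, batch
#' norm, efficient channel attention, dropout, leaky ReLU), 2x2 max pool and
#' flatten, a BiLSTM over the segment sequence, and a linear layer with one
#' sigmoid unit per class trained against the one-hot labels with mean
#' squared error (the paper-default objective) under Adam. Every source of
#' randomness (initialisation, shuffling, dropout) is governed by `seed`.
#'
#' @param batch a `sequence_batch` of training sequences.
#' @param config a [net_config()].
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @param verbose print the per-epoch loss.
#' @return an object of class `emotion_net` with elements `params`, `state`
#'   (batch-norm running moments), `config`, `history` (per-epoch loss),
#'   `dimension`, `seed`.
#' @seealso [predict.emotion_net()], [run_cv()], [evaluate_cohort()]
#' @export
emotion_net <- function(batch, config = net_config(), epochs = 100,
                        lr = 0.001, seed = 1, verbose = FALSE) {
  stopifnot(inherits(batch, "sequence_batch"), inherits(config, "net_config"),
            epochs >= 1)
  X <- batch$inputs
  d <- dim(X)
  if (d[2] != config$seq_len)
    config$seq_len <- d[2]
  Y <- if (config$out_units == 2) batch$labels else
    matrix(batch$label, ncol = 1)
  n <- d[1]
  ini <- init_params(config, in_channels = d[3], seed = derive_seed(seed, 1))
  params <- ini$params; state <- ini$state
  opt <- list(t = 0,
              m = lapply(params, function(p) p * 0),
              v = lapply(params, function(p) p * 0))
  history <- numeric(epochs)
  with_seed(derive_seed(seed, 2), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        fw <- net_forward(params, state, config,
                          X[idx, , , , , drop = FALSE], training = TRUE,
                          collect = TRUE)
        state <- fw$state
        lg <- net_loss_grad(fw$scores, Y[idx, , drop = FALSE], config$loss)
        if (!is.finite(lg$loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        grads <- net_backward(params, config, fw$caches, lg$dlogits)
        up <- adam_step(params, grads, opt, lr)
        params <- up$params; opt <- up$opt
        tot <- tot + lg$loss * length(idx)
      }
      history[ep] <- tot / n
      if (verbose) cat(sprintf("epoch %3d  loss %.5f\n", ep, history[ep]))
    }
  })
  state <- finalize_bn(params, state, config, X)
  structure(list(
    params = params, state = state, config = config,
    history = data.frame(epoch = seq_len(epochs), loss = history),
    dimension = batch$dimension, seed = seed, lr = lr, epochs = epochs,
    n_train = n, call = match.call()
  ), class = "emotion_net")
}

#' Predict from a fitted emotion network
#'
#' Runs the network in evaluation mode (batch-norm running moments, no
#' dropout), which is deterministic for fixed weights and input.
#'
#' @param object an [emotion_net()] fit.
#' @param newdata a `sequence_batch` or an array n x seq_len x bands x 9 x 9.
#' @param type `"score"` for sigmoid outputs, `"class"` for 0/1 decisions.
#' @param chunk sequences scored per forward pass.
#' @param ... unused.
#' @return matrix of scores in (0, 1), or an integer class vector.
#' @export
predict.emotion_net <- function(object, newdata, type = c("score", "class"),
                                chunk = 256, ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "sequence_batch")) newdata$inputs else newdata
  stopifnot(length(dim(X)) == 5)
  n <- dim(X)[1]
  out <- matrix(0, n, object$config$out_units)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    fw <- net_forward(object$params, object$state, object$config,
                      X[idx, , , , , drop = FALSE], training = FALSE)
    out[idx, ] <- fw$scores
  }
  if (type == "class") predict_class(out) else out
}

#' Per-step CNN feature vectors
#'
#' Runs only the convolutional encoder (eval mode) and returns the flattened
#' per-segment feature vectors fed to the recurrent head.
#'
#' @param object an [emotion_net()] fit.
#' @param newdata a `sequence_batch` or input array.
#' @return array n x seq_len x D of encoded features.
#' @export
cnn_encode <- function(object, newdata) {
  X <- if (inherits(newdata, "sequence_batch")) newdata$inputs else newdata
  d <- dim(X)
  n <- d[1]; T <- d[2]
  cfg <- object$config
  g <- gathers_cached(n * T, cfg$kernel)
  F <- batch_to_pixmat(X)
  for (l in 1:4) {
    F <- conv_fwd(F, object$params[[paste0("c", l, ".W")]], g)$Y
    bn <- bn_fwd(F, object$params[[paste0("c", l, ".g")]],
                 object$params[[paste0("c", l, ".b")]],
                 object$state[[paste0("c", l)]], training = FALSE)
    F <- eca_fwd(bn$Y, object$params[[paste0("c", l, ".e")]], n * T, g$P)$Y
    F <- pmax(F, 0) + cfg$leaky_slope * pmin(F, 0)
  }
  pl <- pool_fwd(F, g)
  V <- flat_fwd(pl$M, n * T, g$Po)
  out <- array(0, dim = c(n, T, ncol(V)))
  for (t in seq_len(T)) out[, t, ] <- V[(seq_len(n) - 1L) * T + t, , drop = FALSE]
  out
}

#' @export
print.emotion_net <- function(x, ...) {
  cfg <- x$config
  cat("emotion_net:", x$dimension %||% "?", "classifier\n")
  cat(sprintf("  conv blocks %s (kernel %dx%d, ECA, dropout %.2f, leaky ReLU)\n",
              paste(cfg$conv_channels, collapse = "-"), cfg$kernel,
              cfg$kernel, cfg$dropout))
  cat(sprintf("  %sLSTM hidden %d, %d output unit(s), loss %s\n",
              if (cfg$bidirectional) "Bi" else "", cfg$lstm_hidden,
              cfg$out_units, cfg$loss))
  cat(sprintf("  trained %d epochs on %d sequences, final loss %.5f\n",
              x$epochs, x$n_train, tail(x$history$loss, 1)))
  invisible(x)
}

#' @export
summary.emotion_net <- function(object, ...) {
  np <- sum(vapply(object$params, length, 1L))
  cat(sprintf("emotion_net with %d trainable parameters\n", np))
  print(object)
  invisible(object)
}

#' @export
plot.emotion_net <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = "emotion_net training loss", ...)
  invisible(x)
}

#' Save / load a fitted network
#'
#' The checkpoint is an RDS file accompanied by a JSON sidecar of the
#' architecture configuration.
#'
#' @param object an `emotion_net`.
#' @param path checkpoint path (`.rds`); the sidecar gets extension `.json`.
#' @return `save_model`: the path, invisibly. `load_model`: the restored
#'   `emotion_net`.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "emotion_net"))
  saveRDS(object, path)
  sidecar <- sub("\\.rds$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  writeLines(jsonlite::toJSON(unclass(object$config), auto_unbox = TRUE,
                              digits = NA), sidecar)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "emotion_net"))
  obj
}
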