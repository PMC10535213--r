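#' Network architecture configuration
#'
#' Four convolutional blocks (conv -> batch norm -> efficient channel
#' attention -> dropout -> leaky ReLU, spatial size preserved by
#' same-padding), a 2x2 max pool and flatten, then a bidirectional LSTM whose
#' final forward/backward hidden states feed a linear layer with sigmoid
#' outputs, one unit per class.
#'
#' @param conv_channels widths of the four conv blocks.
#' @param kernel odd spatial kernel size (same-padding).
#' @param dropout dropout probability in `[0, 1)` applied inside each block.
#' @param lstm_hidden hidden units per LSTM direction.
#' @param bidirectional process the sequence in both directions.
#' @param seq_len consecutive segments per input sequence.
#' @param out_units 2 (one sigmoid per class, argmax decision) or 1
#'   (single sigmoid, 0.5 threshold).
#' @param eca_b,eca_gamma parameters of the adaptive attention kernel size
#'   `k = odd(floor(|(log2(C) + b) / gamma|))`.
#' @param leaky_slope negative slope of the leaky ReLU.
#' @param batch_size minibatch size used by the trainer.
#' @param loss `"mse"` (sigmoid + mean squared error, the default) or
#'   `"ce"` (sigmoid + binary cross-entropy, ablation switch).
#' @return an object of class `net_config`.
#' @export
net_config <- function(conv_channels = c(64, 128, 256, 64), kernel = 3,
                       dropout = 0.5, lstm_hidden = 128, bidirectional = TRUE,
                       seq_len = 10, out_units = 2, eca_b = 1, eca_gamma = 2,
                       leaky_slope = 0.01, batch_size = 32,
                       loss = c("mse", "ce")) {
  loss <- match.arg(loss)
  if (length(conv_channels) != 4 || any(conv_channels < 1))
    stop("conv_channels must be four positive widths")
  if (kernel %% 2 != 1 || kernel < 1) stop("kernel must be odd")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (seq_len < 1) stop("seq_len must be >= 1")
  if (!out_units %in% 1:2) stop("out_units must be 1 or 2")
  if (eca_gamma < 1) stop("eca_gamma must be >= 1")
  structure(list(
    conv_channels = as.integer(conv_channels), kernel = as.integer(kernel),
    dropout = dropout, lstm_hidden = as.integer(lstm_hidden),
    bidirectional = isTRUE(bidirectional), seq_len = as.integer(seq_len),
    out_units = as.integer(out_units), eca_b = eca_b, eca_gamma = eca_gamma,
    leaky_slope = leaky_slope, batch_size = as.integer(batch_size),
    loss = loss
  ), class = "net_config")
}

#' Adaptive attention kernel size
#'
#' The efficient-channel-attention kernel adapts to the channel count:
#' `t = floor(|(log2(C) + b) / gamma|)`, bumped to the next odd number
#' (minimum 1).
#'
#' @param C channel count (`>= 1`).
#' @param b,gamma kernel-size parameters (defaults 1 and 2).
#' @return odd integer kernel size.
#' @export
eca_kernel_size <- function(C, b = 1, gamma = 2) {
  if (any(C < 1)) stop("C must be >= 1")
  t <- floor(abs((log2(C) + b) / gamma))
  k <- ifelse(t %% 2 == 1, t, t + 1)
  as.integer(pmax(k, 1))
}

#' Efficient channel attention forward pass
#'
#' Global average pooling per channel, a 1-D convolution of adaptive odd
#' kernel size across the channel axis, a sigmoid gate, and broadcast
#' multiplication with the input.
#'
#' @param x array of shape N x C x H x W.
#' @param w kernel weights of length [eca_kernel_size()]`(C)`; defaults to a
#'   uniform averaging kernel.
#' @param b,gamma kernel-size parameters.
#' @return list with `out` (same shape as `x`) and `weights` (N x C gate
#'   matrix, all values in (0, 1)).
#' @export
eca_forward <- function(x, w = NULL, b = 1, gamma = 2) {
  stopifnot(length(dim(x)) == 4)
  C <- dim(x)[2]
  k <- eca_kernel_size(C, b, gamma)
  if (is.null(w)) w <- rep(1 / k, k)
  if (length(w) != k) stop("w must have length ", k)
  g <- apply(x, c(1, 2), mean)
  if (is.null(dim(g))) g <- matrix(g, nrow = dim(x)[1])
  a <- 1 / (1 + exp(-chan_conv1d(g, w)))
  out <- x
  for (ci in seq_len(C)) out[, ci, , ] <- x[, ci, , , drop = FALSE] * a[, ci]
  list(out = out, weights = a)
}

# 1-D convolution across the channel axis of an N x C matrix, zero padded.
chan_conv1d <- function(G, w) {
  C <- ncol(G); k <- length(w); h <- (k - 1) %/% 2
  S <- matrix(0, nrow(G), C)
  for (j in seq_len(k)) {
    off <- j - h - 1
    src <- seq_len(C) + off
    ok <- src >= 1 & src <= C
    if (any(ok)) S[, which(ok)] <- S[, which(ok)] + w[j] * G[, src[ok], drop = FALSE]
  }
  S
}
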