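# Internal layer primitives for the emotion network.
#
# Feature maps live in "pixel-major" matrices F of shape (N * P, C): row
# (img - 1) * P + p holds pixel p (column-major within the H x W plane) of
# image `img`; columns are channels. Convolutions become 9 shifted GEMMs,
# which keeps everything inside BLAS.

sigm <- function(x) 1 / (1 + exp(-x))

# ---- gather-index machinery -------------------------------------------------

# pixel map for a spatial shift (dr, dc) on an H x W plane; NA = padding
pix_shift_map <- function(dr, dc, H = 9, W = 9) {
  p <- seq_len(H * W)
  r <- (p - 1) %% H + 1
  cc <- (p - 1) %/% H + 1
  rr <- r + dr; ccc <- cc + dc
  ok <- rr >= 1 & rr <= H & ccc >= 1 & ccc <= W
  ifelse(ok, (ccc - 1) * H + rr, NA_integer_)
}

# expand a per-pixel map to a gather index over N images; 0 marks padding
expand_gather <- function(map, N, P) {
  map <- as.integer(map)
  base <- rep.int((seq_len(N) - 1L) * as.integer(P), rep.int(length(map), N))
  idx <- base + rep.int(map, N)
  idx[is.na(idx)] <- 0L
  idx
}

conv_offsets <- function(kernel) {
  h <- (kernel - 1) %/% 2
  expand.grid(dr = -h:h, dc = -h:h)
}

# all gather indices needed for one batch of N images; offset k and offset
# K + 1 - k are spatial opposites, which the conv adjoint exploits
make_gathers <- function(N, kernel = 3, H = 9, W = 9) {
  offs <- conv_offsets(kernel)
  P <- H * W
  fwd <- vapply(seq_len(nrow(offs)), function(k)
    expand_gather(pix_shift_map(offs$dr[k], offs$dc[k], H, W), N, P),
    integer(N * P))
  Ho <- H %/% 2; Wo <- W %/% 2
  pool <- lapply(1:4, function(j) {
    a <- (j - 1) %% 2; b <- (j - 1) %/% 2
    q <- seq_len(Ho * Wo)
    rq <- (q - 1) %% Ho + 1; cq <- (q - 1) %/% Ho + 1
    map <- (2 * cq - 2 + b) * H + (2 * rq - 1 + a)
    expand_gather(map, N, P)
  })
  list(fwd = fwd, pool = pool, P = P, Po = Ho * Wo, N = N, K = nrow(offs))
}

# gather tables depend only on (N, kernel); memoise across batches
.gather_cache <- new.env(parent = emptyenv())
gathers_cached <- function(N, kernel = 3, H = 9, W = 9) {
  key <- paste(N, kernel, H, W, sep = "_")
  g <- .gather_cache[[key]]
  if (is.null(g)) {
    g <- make_gathers(N, kernel, H, W)
    if (length(ls(.gather_cache)) > 8) rm(list = ls(.gather_cache),
                                          envir = .gather_cache)
    .gather_cache[[key]] <- g
  }
  g
}

# ---- convolution ------------------------------------------------------------
#
# im2col form: weights live as a (K * Cin) x Cout matrix so the whole layer
# is one wide GEMM; the gather/scatter runs in C++.

conv_fwd <- function(F, W2, g) {
  X2 <- cpp_im2col(F, g$fwd)
  list(Y = X2 %*% W2, X2 = X2)
}

conv_bwd <- function(X2, dY, W2, g, Cin) {
  dW2 <- crossprod(X2, dY)
  dX <- cpp_col2im(dY %*% t(W2), g$fwd, Cin)
  list(dX = dX, dW = dW2)
}

# ---- batch normalisation ----------------------------------------------------

bn_fwd <- function(X, g, b, state, training, momentum = 0.1, eps = 1e-5) {
  n <- nrow(X)
  if (training) {
    m <- colMeans(X)
    v <- colMeans(X^2) - m^2
    state$rm <- (1 - momentum) * state$rm + momentum * m
    state$rv <- (1 - momentum) * state$rv + momentum * v * n / max(n - 1, 1)
  } else {
    m <- state$rm; v <- state$rv
  }
  istd <- 1 / sqrt(v + eps)
  # rep(..., each = n) matches the column-major layout, cheaper than
  # matrix(byrow = TRUE)
  xhat <- (X - rep(m, each = n)) * rep(istd, each = n)
  Y <- xhat * rep(g, each = n) + rep(b, each = n)
  list(Y = Y, xhat = xhat, istd = istd, state = state)
}

bn_bwd <- function(dY, cache, g) {
  n <- nrow(dY); C <- ncol(dY)
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- dY * rep(g, each = n)
  mu1 <- colMeans(dxhat)
  mu2 <- colMeans(dxhat * xhat)
  dX <- (dxhat - rep(mu1, each = n) - xhat * rep(mu2, each = n)) *
    rep(cache$istd, each = n)
  list(dX = dX, dg = dg, db = db)
}

# ---- efficient channel attention -------------------------------------------

eca_fwd <- function(F, w, N, P) {
  C <- ncol(F)
  G <- colMeans(array(F, c(P, N, C)))            # N x C channel descriptors
  if (is.null(dim(G))) G <- matrix(G, N, C)
  A <- sigm(chan_conv1d(G, w))
  rep_idx <- rep(seq_len(N), each = P)
  list(Y = F * A[rep_idx, , drop = FALSE], G = G, A = A, rep_idx = rep_idx)
}

eca_bwd <- function(dY, F, cache, w, N, P) {
  C <- ncol(F)
  A <- cache$A; G <- cache$G
  dF <- dY * A[cache$rep_idx, , drop = FALSE]
  dA <- colSums(array(dY * F, c(P, N, C)))
  if (is.null(dim(dA))) dA <- matrix(dA, N, C)
  dS <- dA * A * (1 - A)
  k <- length(w); h <- (k - 1) %/% 2
  dw <- numeric(k)
  dG <- matrix(0, N, C)
  for (j in seq_len(k)) {
    off <- j - h - 1
    src <- seq_len(C) + off
    ok <- src >= 1 & src <= C
    if (any(ok)) {
      dw[j] <- sum(dS[, which(ok), drop = FALSE] * G[, src[ok], drop = FALSE])
      dG[, src[ok]] <- dG[, src[ok], drop = FALSE] +
        w[j] * dS[, which(ok), drop = FALSE]
    }
  }
  list(dX = dF + dG[cache$rep_idx, , drop = FALSE] / P, dw = dw)
}

# ---- max pool + flatten -----------------------------------------------------

pool_fwd <- function(F, g) {
  M <- F[g$pool[[1]], , drop = FALSE]
  K <- matrix(1L, nrow(M), ncol(M))
  for (j in 2:4) {
    Pj <- F[g$pool[[j]], , drop = FALSE]
    upd <- Pj > M
    M[upd] <- Pj[upd]
    K[upd] <- j
  }
  list(M = M, K = K)
}

pool_bwd <- function(dM, K, g, n_rows, C) {
  dF <- matrix(0, n_rows, C)
  for (j in 1:4) {
    sel <- dM * (K == j)
    dF[g$pool[[j]], ] <- dF[g$pool[[j]], , drop = FALSE] + sel
  }
  dF
}

flat_fwd <- function(M, N, Po) {
  C <- ncol(M)
  V <- t(matrix(aperm(array(M, c(Po, N, C)), c(1, 3, 2)), Po * C, N))
  V
}

flat_bwd <- function(dV, N, Po, C) {
  dA <- aperm(array(t(dV), c(Po, C, N)), c(1, 3, 2))
  dim(dA) <- c(Po * N, C)
  dA
}

# ---- LSTM -------------------------------------------------------------------

lstm_fwd <- function(V, n, T, Wx, Wh, b, reverse = FALSE) {
  H <- nrow(Wh)
  ord <- if (reverse) rev(seq_len(T)) else seq_len(T)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  caches <- vector("list", T)
  for (s in seq_len(T)) {
    t <- ord[s]
    X <- V[(seq_len(n) - 1L) * T + t, , drop = FALSE]
    Z <- X %*% Wx + h %*% Wh + matrix(b, n, 4 * H, byrow = TRUE)
    i <- sigm(Z[, seq_len(H), drop = FALSE])
    f <- sigm(Z[, H + seq_len(H), drop = FALSE])
    g <- tanh(Z[, 2 * H + seq_len(H), drop = FALSE])
    o <- sigm(Z[, 3 * H + seq_len(H), drop = FALSE])
    cn <- f * cc + i * g
    tc <- tanh(cn)
    caches[[s]] <- list(X = X, Hprev = h, Cprev = cc, i = i, f = f, g = g,
                        o = o, tc = tc, t = t)
    cc <- cn
    h <- o * tc
  }
  list(h_final = h, caches = caches, ord = ord)
}

lstm_bwd <- function(dh_final, fw, n, T, D, Wx, Wh) {
  H <- nrow(Wh)
  dWx <- matrix(0, D, 4 * H); dWh <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dV <- matrix(0, n * T, D)
  dh <- dh_final
  dc <- matrix(0, n, H)
  for (s in rev(seq_len(T))) {
    ca <- fw$caches[[s]]
    do <- dh * ca$tc
    dc <- dc + dh * ca$o * (1 - ca$tc^2)
    di <- dc * ca$g
    dg <- dc * ca$i
    df <- dc * ca$Cprev
    dc <- dc * ca$f
    dZ <- cbind(di * ca$i * (1 - ca$i), df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2), do * ca$o * (1 - ca$o))
    dWx <- dWx + crossprod(ca$X, dZ)
    dWh <- dWh + crossprod(ca$Hprev, dZ)
    db <- db + colSums(dZ)
    dV[(seq_len(n) - 1L) * T + ca$t, ] <-
      dV[(seq_len(n) - 1L) * T + ca$t, , drop = FALSE] + dZ %*% t(Wx)
    dh <- dZ %*% t(Wh)
  }
  list(dV = dV, dWx = dWx, dWh = dWh, db = db)
}
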