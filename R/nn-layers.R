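# Minimal feed-forward layer zoo used by the residual classifier.
#
# Activations are 4-d arrays with dim c(H, W, C, N): spatial rows, spatial
# columns, channels, batch. Convolution is im2col + one BLAS matmul; every
# layer has a matching backward pass. No external deep-learning framework is
# involved, so training is exactly reproducible from an integer seed.

# ---- padding -----------------------------------------------------------

pad_hw <- function(A, pt, pb, pl, pr) {
  if (pt + pb + pl + pr == 0L) return(A)
  d <- dim(A)
  out <- array(0, c(d[1] + pt + pb, d[2] + pl + pr, d[3], d[4]))
  out[pt + seq_len(d[1]), pl + seq_len(d[2]), , ] <- A
  out
}

unpad_hw <- function(A, pt, pb, pl, pr) {
  if (pt + pb + pl + pr == 0L) return(A)
  d <- dim(A)
  A[pt + seq_len(d[1] - pt - pb), pl + seq_len(d[2] - pl - pr), , ,
    drop = FALSE]
}

# ---- im2col convolution ------------------------------------------------

# Patch matrix: rows index (outH, outW, N) column-major, columns index
# (channel within kernel-offset block), offset blocks ordered (dy fast, dx).
im2col <- function(Apad, kh, kw, sh, sw) {
  d <- dim(Apad)
  outH <- (d[1] - kh) %/% sh + 1L
  outW <- (d[2] - kw) %/% sw + 1L
  C <- d[3]; N <- d[4]
  P <- matrix(0, outH * outW * N, kh * kw * C)
  for (dx in seq_len(kw)) {
    cols <- (seq_len(outW) - 1L) * sw + dx
    for (dy in seq_len(kh)) {
      rows <- (seq_len(outH) - 1L) * sh + dy
      S <- Apad[rows, cols, , , drop = FALSE]
      S <- aperm(S, c(1L, 2L, 4L, 3L))       # (outH, outW, N, C)
      dim(S) <- c(outH * outW * N, C)
      blk <- (dx - 1L) * kh + dy
      P[, ((blk - 1L) * C + 1L):(blk * C)] <- S
    }
  }
  list(P = P, outH = outH, outW = outW)
}

col2im <- function(dP, dimApad, kh, kw, sh, sw, outH, outW) {
  C <- dimApad[3]; N <- dimApad[4]
  dApad <- array(0, dimApad)
  for (dx in seq_len(kw)) {
    cols <- (seq_len(outW) - 1L) * sw + dx
    for (dy in seq_len(kh)) {
      rows <- (seq_len(outH) - 1L) * sh + dy
      blk <- (dx - 1L) * kh + dy
      S <- dP[, ((blk - 1L) * C + 1L):(blk * C), drop = FALSE]
      dim(S) <- c(outH, outW, N, C)
      S <- aperm(S, c(1L, 2L, 4L, 3L))       # (outH, outW, C, N)
      dApad[rows, cols, , ] <- dApad[rows, cols, , , drop = FALSE] + S
    }
  }
  dApad
}

# Convolution layer. `W` is (kh*kw*Cin) x Cout, `b` length Cout. Even kernel
# sizes get asymmetric "same" padding (0 before, 1 after); odd sizes the
# usual symmetric (k-1)/2.
conv_layer <- function(in_ch, out_ch, kh, kw, stride = c(1L, 1L),
                       pad = NULL) {
  if (is.null(pad)) {
    pv <- function(k) if (k %% 2L == 1L) c((k - 1L) %/% 2L, (k - 1L) %/% 2L)
                      else c((k - 2L) %/% 2L, k %/% 2L)
    pad <- c(pv(kh), pv(kw))  # top, bottom, left, right
  }
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, kh = kh, kw = kw,
       stride = as.integer(stride), pad = as.integer(pad),
       W = matrix(0, kh * kw * in_ch, out_ch), b = numeric(out_ch))
}

conv_forward <- function(layer, A) {
  Apad <- pad_hw(A, layer$pad[1], layer$pad[2], layer$pad[3], layer$pad[4])
  ic <- im2col(Apad, layer$kh, layer$kw, layer$stride[1], layer$stride[2])
  Y <- ic$P %*% layer$W
  Y <- sweep(Y, 2L, layer$b, "+")
  N <- dim(A)[4]
  dim(Y) <- c(ic$outH, ic$outW, N, layer$out_ch)
  out <- aperm(Y, c(1L, 2L, 4L, 3L))
  list(out = out,
       cache = list(P = ic$P, dimApad = dim(Apad), dimA = dim(A),
                    outH = ic$outH, outW = ic$outW))
}

conv_backward <- function(layer, cache, dOut) {
  dY <- aperm(dOut, c(1L, 2L, 4L, 3L))       # (outH, outW, N, Cout)
  dim(dY) <- c(cache$outH * cache$outW * dim(dOut)[4], layer$out_ch)
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- dY %*% t(layer$W)
  dApad <- col2im(dP, cache$dimApad, layer$kh, layer$kw,
                  layer$stride[1], layer$stride[2], cache$outH, cache$outW)
  dA <- unpad_hw(dApad, layer$pad[1], layer$pad[2], layer$pad[3], layer$pad[4])
  list(dIn = dA, grads = list(W = dW, b = db))
}

# ---- batch normalisation ----------------------------------------------

bn_layer <- function(ch, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", ch = ch, momentum = momentum, eps = eps,
       gamma = rep(1, ch), beta = numeric(ch),
       running_mean = numeric(ch), running_var = rep(1, ch))
}

# Flatten (H, W, C, N) to a (H*W*N) x C matrix and back.
to_ch_matrix <- function(A) {
  d <- dim(A)
  Am <- aperm(A, c(1L, 2L, 4L, 3L))
  dim(Am) <- c(d[1] * d[2] * d[4], d[3])
  Am
}

from_ch_matrix <- function(Am, d) {
  dim(Am) <- c(d[1], d[2], d[4], d[3])
  aperm(Am, c(1L, 2L, 4L, 3L))
}

bn_forward <- function(layer, A, training) {
  d <- dim(A)
  Am <- to_ch_matrix(A)
  if (training) {
    mu <- colMeans(Am)
    xc <- sweep(Am, 2L, mu)
    v <- colMeans(xc^2)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
    xc <- sweep(Am, 2L, mu)
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xc, 2L, invstd, "*")
  Ym <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
  list(out = from_ch_matrix(Ym, d), layer = layer,
       cache = list(xhat = xhat, invstd = invstd, d = d,
                    training = training))
}

bn_backward <- function(layer, cache, dOut) {
  dYm <- to_ch_matrix(dOut)
  xhat <- cache$xhat
  mrows <- nrow(dYm)
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2L, layer$gamma, "*")
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dXm <- sweep(dxhat, 2L, s1 / mrows) -
      sweep(xhat, 2L, s2 / mrows, "*")
    dXm <- sweep(dXm, 2L, cache$invstd, "*")
  } else {
    dXm <- sweep(dxhat, 2L, cache$invstd, "*")
  }
  list(dIn = from_ch_matrix(dXm, cache$d),
       grads = list(gamma = dgamma, beta = dbeta))
}

# ---- simple layers -----------------------------------------------------

relu_forward <- function(A) {
  mask <- A > 0
  list(out = A * mask, cache = mask)
}
relu_backward <- function(mask, dOut) dOut * mask

gap_forward <- function(A) {
  d <- dim(A)
  Am <- to_ch_matrix(A)                       # (H*W*N) x C, N slow? no:
  # rows of Am index (H, W, N): use rowsum over batch index
  bidx <- rep(seq_len(d[4]), each = d[1] * d[2])
  out <- rowsum(Am, bidx) / (d[1] * d[2])     # N x C
  rownames(out) <- NULL
  list(out = out, cache = d)
}
gap_backward <- function(d, dOut) {
  dAm <- dOut[rep(seq_len(d[4]), each = d[1] * d[2]), , drop = FALSE] /
    (d[1] * d[2])
  from_ch_matrix(dAm, d)
}

dense_layer <- function(in_units, out_units, head = FALSE) {
  list(type = "dense", W = matrix(0, in_units, out_units),
       b = numeric(out_units), head = head)
}
dense_forward <- function(layer, X) {
  list(out = sweep(X %*% layer$W, 2L, layer$b, "+"), cache = X)
}
dense_backward <- function(layer, X, dOut) {
  list(dIn = tcrossprod(dOut, layer$W),
       grads = list(W = crossprod(X, dOut), b = colSums(dOut)))
}

# ---- loss --------------------------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Mean cross-entropy over the batch; labels in {0, 1} map to columns 1/2.
crossentropy_loss <- function(logits, labels) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = P)
}
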