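# Low-level differentiable ops on [C, T, M] arrays (channels, time, batch).
# Every forward returns list(out, cache); every backward consumes the cache
# and the upstream gradient and returns gradients for inputs and parameters.
# Correctness is pinned by finite-difference tests.

# ---- 1-D convolution ----------------------------------------------------

# "same" padding for kernel k, dilation d: total pad (k-1)*d, split evenly.
conv1d_pad <- function(k, dilation) {
  total <- (k - 1) * dilation
  c(left = floor(total / 2), right = total - floor(total / 2))
}

conv1d_out_len <- function(t_in, stride) ceiling(t_in / stride)

# x: [C_in, T, M]; w: [C_out, C_in, K]; b: [C_out]
conv1d_forward <- function(x, w, b, stride = 1, dilation = 1) {
  dx <- dim(x)
  c_in <- dx[1]; t_in <- dx[2]; m <- dx[3]
  if (t_in < 1) stopf("zero-length input to convolution")
  c_out <- dim(w)[1]; k <- dim(w)[3]
  stopifnot(dim(w)[2] == c_in)
  pad <- conv1d_pad(k, dilation)
  t_out <- conv1d_out_len(t_in, stride)
  xp <- array(0, dim = c(c_in, t_in + pad[1] + pad[2], m))
  xp[, pad[1] + seq_len(t_in), ] <- x
  ymat <- matrix(0, nrow = c_out, ncol = t_out * m)
  base_idx <- (seq_len(t_out) - 1) * stride + 1
  for (kk in seq_len(k)) {
    idx <- base_idx + (kk - 1) * dilation
    xs <- matrix(xp[, idx, , drop = FALSE], nrow = c_in)
    ymat <- ymat + matrix(w[, , kk], nrow = c_out) %*% xs
  }
  y <- array(ymat + b, dim = c(c_out, t_out, m))
  list(out = y, cache = list(xp = xp, dims = dx, w = w, stride = stride,
                             dilation = dilation, pad = pad, t_out = t_out))
}

conv1d_backward <- function(dy, cache) {
  w <- cache$w
  c_out <- dim(w)[1]; c_in <- dim(w)[2]; k <- dim(w)[3]
  t_in <- cache$dims[2]; m <- cache$dims[3]
  t_out <- cache$t_out
  dymat <- matrix(dy, nrow = c_out)
  dw <- array(0, dim = dim(w))
  dxp <- array(0, dim = dim(cache$xp))
  base_idx <- (seq_len(t_out) - 1) * cache$stride + 1
  for (kk in seq_len(k)) {
    idx <- base_idx + (kk - 1) * cache$dilation
    xs <- matrix(cache$xp[, idx, , drop = FALSE], nrow = c_in)
    dw[, , kk] <- dymat %*% t(xs)
    contrib <- t(matrix(w[, , kk], nrow = c_out)) %*% dymat  # [C_in, t_out*m]
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] +
      array(contrib, dim = c(c_in, t_out, m))
  }
  db <- rowSums(dymat)
  dx <- dxp[, cache$pad[1] + seq_len(t_in), , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

# ---- ReLU ---------------------------------------------------------------

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(dy, cache) dy * cache

# ---- Batch normalization (per channel over time x batch) ---------------

bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       run_mean = rep(0, channels), run_var = rep(1, channels))
}

# p: list(gamma, beta); state: list(run_mean, run_var) updated when training
bn_forward <- function(x, p, state, training = TRUE, momentum = 0.1,
                       eps = 1e-5) {
  d <- dim(x)
  n <- d[2] * d[3]
  xm <- matrix(x, nrow = d[1])
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    state$run_mean <- (1 - momentum) * state$run_mean + momentum * mu
    state$run_var <- (1 - momentum) * state$run_var + momentum * v
  } else {
    mu <- state$run_mean
    v <- state$run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv_sd
  y <- array(p$gamma * xhat + p$beta, dim = d)
  list(out = y, state = state,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = p$gamma, d = d,
                    n = n, training = training))
}

bn_backward <- function(dy, cache) {
  d <- cache$d
  dym <- matrix(dy, nrow = d[1])
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * cache$gamma
  if (cache$training) {
    n <- cache$n
    dx <- (cache$inv_sd / n) *
      (n * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dx <- dxhat * cache$inv_sd
  }
  list(dx = array(dx, dim = d), dgamma = dgamma, dbeta = dbeta)
}

# ---- Average pooling (window k, stride 1, same padding) -----------------

avgpool_forward <- function(x, k = 3) {
  d <- dim(x)
  pad <- conv1d_pad(k, 1)
  xp <- array(0, dim = c(d[1], d[2] + pad[1] + pad[2], d[3]))
  xp[, pad[1] + seq_len(d[2]), ] <- x
  y <- array(0, dim = d)
  for (kk in seq_len(k)) {
    y <- y + xp[, (kk - 1) + seq_len(d[2]), , drop = FALSE]
  }
  y <- y / k
  list(out = y, cache = list(k = k, d = d, pad = pad))
}

avgpool_backward <- function(dy, cache) {
  d <- cache$d; k <- cache$k; pad <- cache$pad
  dxp <- array(0, dim = c(d[1], d[2] + pad[1] + pad[2], d[3]))
  for (kk in seq_len(k)) {
    idx <- (kk - 1) + seq_len(d[2])
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] + dy / k
  }
  dxp[, pad[1] + seq_len(d[2]), , drop = FALSE]
}

# ---- Dense (rows = batch) ----------------------------------------------

# z: [M, D_in]; w: [D_in, D_out]; b: [D_out]
dense_forward <- function(z, w, b) {
  list(out = z %*% w + matrix(b, nrow(z), length(b), byrow = TRUE),
       cache = list(z = z, w = w))
}

dense_backward <- function(dy, cache) {
  list(dz = dy %*% t(cache$w), dw = crossprod(cache$z, dy), db = colSums(dy))
}

# Row-wise, shift-invariant softmax
softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}
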