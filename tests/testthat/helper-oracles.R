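# Reference implementations coded independently of the package internals:
# explicit per-unit arithmetic for single steps, and a plain peephole-forget
# LSTM for the zeroed-global-access equivalence.

ref_global_step <- function(x, c_prev, h_prev, p) {
  dh <- length(c_prev)
  f <- i <- o <- cand <- cc <- hh <- numeric(dh)
  for (u in seq_len(dh)) {
    zf <- c(c_prev, h_prev, x)
    zio <- c(h_prev, x)
    f[u] <- 1 / (1 + exp(-(sum(zf * p$w_f[, u]) + p$b_f[u])))
    i[u] <- 1 / (1 + exp(-(sum(zio * p$w_i[, u]) + p$b_i[u])))
    cand[u] <- tanh(sum(zio * p$w_c[, u]) + p$b_c[u])
    o[u] <- 1 / (1 + exp(-(sum(zio * p$w_o[, u]) + p$b_o[u])))
    cc[u] <- f[u] * c_prev[u] + i[u] * cand[u]
    hh[u] <- o[u] * tanh(cc[u])
  }
  list(c = cc, h = hh)
}

ref_intra_step <- function(x, h_g, c_prev, h_prev, p) {
  dh <- length(c_prev)
  cc <- hh <- numeric(dh)
  for (u in seq_len(dh)) {
    zf <- c(c_prev, h_prev, h_g, x)
    zio <- c(h_prev, h_g, x)
    f <- 1 / (1 + exp(-(sum(zf * p$w_f[, u]) + p$b_f[u])))
    i <- 1 / (1 + exp(-(sum(zio * p$w_i[, u]) + p$b_i[u])))
    cand <- tanh(sum(zio * p$w_c[, u]) + p$b_c[u])
    o <- 1 / (1 + exp(-(sum(zio * p$w_o[, u]) + p$b_o[u])))
    cc[u] <- f * c_prev[u] + i * cand
    hh[u] <- o * tanh(cc[u])
  }
  list(c = cc, h = hh)
}

# plain unidirectional LSTM whose forget gate reads the previous cell state
ref_plain_lstm <- function(xs, p_f, p_i, p_c, p_o, b, dh) {
  t_len <- length(xs)
  h <- c <- rep(0, dh)
  out <- vector("list", t_len)
  for (t in seq_len(t_len)) {
    zf <- c(c, h, xs[[t]])
    zio <- c(h, xs[[t]])
    f <- plogis(as.vector(zf %*% p_f) + b$f)
    i <- plogis(as.vector(zio %*% p_i) + b$i)
    cand <- tanh(as.vector(zio %*% p_c) + b$c)
    o <- plogis(as.vector(zio %*% p_o) + b$o)
    c <- f * c + i * cand
    h <- o * tanh(c)
    out[[t]] <- h
  }
  out
}

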