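# Reference oracles live in helper-oracles.R.

test_that("zero-parameter cells hit the sigmoid/tanh fixed values", {
  dh <- 3; d <- 2
  p <- leadwise:::gate_init(2 * dh + d, dh + d, dh + d, dh)
  for (nm in names(p)) p[[nm]][] <- 0
  x <- matrix(rnorm(d), 1, d)
  zero <- matrix(0, 1, dh)
  s <- global_cell_step(x, zero, zero, p)
  expect_equal(as.vector(s$c), rep(0, dh))
  expect_equal(as.vector(s$h), rep(0, dh))
  expect_equal(as.vector(s$cache$f), rep(0.5, dh))
  expect_equal(as.vector(s$cache$i), rep(0.5, dh))
  expect_equal(as.vector(s$cache$o), rep(0.5, dh))

  cp <- matrix(c(0.4, -1.2, 2.0), 1, dh)
  s2 <- global_cell_step(x, cp, zero, p)
  expect_equal(s2$c, 0.5 * cp)                 # C_t = f (*) C_{t-1}
  expect_equal(s2$h, 0.5 * tanh(0.5 * cp))

  pi_ <- leadwise:::gate_init(3 * dh + d, 2 * dh + d, 2 * dh + d, dh)
  for (nm in names(pi_)) pi_[[nm]][] <- 0
  si <- intra_cell_step(x, matrix(rnorm(dh), 1, dh), zero, zero, pi_)
  expect_equal(as.vector(si$h), rep(0, dh))
})

test_that("single steps match independent per-unit evaluations to 1e-10", {
  dh <- 2; d <- 1
  pg <- random_gates(2 * dh + d, dh + d, dh + d, dh, seed = 5)
  x <- matrix(c(0.7), 1, d)
  cp <- matrix(c(0.3, -0.5), 1, dh)
  hp <- matrix(c(-0.2, 0.8), 1, dh)
  got <- global_cell_step(x, cp, hp, pg)
  ref <- ref_global_step(as.vector(x), as.vector(cp), as.vector(hp), pg)
  expect_equal(as.vector(got$c), ref$c, tolerance = 1e-10)
  expect_equal(as.vector(got$h), ref$h, tolerance = 1e-10)

  pi_ <- random_gates(3 * dh + d, 2 * dh + d, 2 * dh + d, dh, seed = 6)
  hg <- matrix(c(0.6, -0.9), 1, dh)
  goti <- intra_cell_step(x, hg, cp, hp, pi_)
  refi <- ref_intra_step(as.vector(x), as.vector(hg), as.vector(cp),
                         as.vector(hp), pi_)
  expect_equal(as.vector(goti$c), refi$c, tolerance = 1e-10)
  expect_equal(as.vector(goti$h), refi$h, tolerance = 1e-10)
})

test_that("zeroed global-access weights reduce intra cells to a plain bidirectional LSTM", {
  dh <- 3; d <- 2; t_len <- 5; m <- 1; n <- 2
  cfg <- recurrent_config(hidden_size = dh, share_intra = TRUE)
  set.seed(9)
  p_rnn <- leadwise:::rnn_init(d, n, cfg)
  # zero every weight row that multiplies the global hidden state
  for (dir in c("fwd", "bwd")) {
    g <- p_rnn$intra[[dir]]
    g$w_f[2 * dh + seq_len(dh), ] <- 0   # zf = [c, h, h_g, x]
    g$w_i[dh + seq_len(dh), ] <- 0       # zio = [h, h_g, x]
    g$w_o[dh + seq_len(dh), ] <- 0
    g$w_c[dh + seq_len(dh), ] <- 0
    p_rnn$intra[[dir]] <- g
  }
  feats <- random_feats(n, d, t_len, m, seed = 10)
  out <- run_group(feats, p_rnn, cfg)

  for (i in seq_len(n)) {
    xs <- lapply(seq_len(t_len), function(t) as.vector(feats[[i]][, t, 1]))
    for (dir in c("fwd", "bwd")) {
      g <- p_rnn$intra[[dir]]
      keep_f <- c(seq_len(2 * dh), 3 * dh + seq_len(d))
      keep_io <- c(seq_len(dh), 2 * dh + seq_len(d))
      b <- list(f = g$b_f, i = g$b_i, c = g$b_c, o = g$b_o)
      seq_order <- if (dir == "fwd") seq_len(t_len) else rev(seq_len(t_len))
      ref <- ref_plain_lstm(xs[seq_order],
                            g$w_f[keep_f, ], g$w_i[keep_io, ],
                            g$w_c[keep_io, ], g$w_o[keep_io, ], b, dh)
      for (k in seq_len(t_len)) {
        t_actual <- seq_order[k]
        expect_equal(as.vector(out$intra[[i]][[dir]][[t_actual]]), ref[[k]],
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("the group runner wires one global and n intra cells as specified", {
  dh <- 4; d <- 3; t_len <- 4; m <- 2; n <- 12
  cfg <- recurrent_config(hidden_size = dh)
  set.seed(12)
  p_rnn <- leadwise:::rnn_init(d, n, cfg)
  feats <- random_feats(n, d, t_len, m, seed = 13)
  out <- run_group(feats, p_rnn, cfg)
  expect_length(out$intra, 12)
  expect_length(out$global$fwd, t_len)
  expect_length(out$global$bwd, t_len)

  # permuting leads leaves the global sequences unchanged (summed input)
  # and permutes the intra sequences identically (shared parameters)
  perm <- sample(n)
  out_p <- run_group(feats[perm], p_rnn, cfg)
  for (t in seq_len(t_len)) {
    expect_equal(out_p$global$fwd[[t]], out$global$fwd[[t]], tolerance = 1e-12)
  }
  for (i in seq_len(n)) {
    expect_equal(out_p$intra[[i]]$fwd, out$intra[[perm[i]]]$fwd,
                 tolerance = 1e-12)
  }

  # hidden coordinates bounded by the sigmoid-tanh product
  all_h <- unlist(c(out$global, lapply(out$intra, unlist)))
  expect_true(all(abs(all_h) < 1))

  expect_error(run_group(feats[1], p_rnn, cfg), "at least 2")
})

test_that("a length-one sequence reduces to the single-step operations", {
  dh <- 3; d <- 2; m <- 2; n <- 2
  cfg <- recurrent_config(hidden_size = dh)
  set.seed(15)
  p_rnn <- leadwise:::rnn_init(d, n, cfg)
  feats <- random_feats(n, d, 1, m, seed = 16)
  out <- run_group(feats, p_rnn, cfg)
  x1 <- t(matrix(feats[[1]][, 1, ], nrow = d))
  x2 <- t(matrix(feats[[2]][, 1, ], nrow = d))
  zero <- matrix(0, m, dh)
  gs <- global_cell_step(x1 + x2, zero, zero, p_rnn$global$fwd)
  expect_equal(out$global$fwd[[1]], gs$h, tolerance = 1e-12)
  is1 <- intra_cell_step(x1, gs$h, zero, zero, p_rnn$intra$fwd)
  expect_equal(out$intra[[1]]$fwd[[1]], is1$h, tolerance = 1e-12)
})

test_that("one global+intra step backpropagates to 1e-4 of finite differences", {
  dh <- 2; d <- 2; m <- 1
  pg <- random_gates(2 * dh + d, dh + d, dh + d, dh, seed = 21)
  pi_ <- random_gates(3 * dh + d, 2 * dh + d, 2 * dh + d, dh, seed = 22)
  set.seed(23)
  x <- matrix(rnorm(d), m, d)
  zero <- matrix(0, m, dh)
  loss_fn <- function(pg, pi_, x) {
    g <- global_cell_step(x, zero, zero, pg)
    i <- intra_cell_step(x, g$h, zero, zero, pi_)
    sum(i$h^2) / 2
  }
  g <- global_cell_step(x, zero, zero, pg)
  i <- intra_cell_step(x, g$h, zero, zero, pi_)
  ib <- leadwise:::intra_cell_backward(i$h, zero, i$cache, pi_)
  gb <- leadwise:::global_cell_backward(ib$dh_g, zero, g$cache, pg)
  eps <- 1e-6
  for (probe in list(list("g", "w_f", 3), list("g", "w_c", 5),
                     list("i", "w_f", 7), list("i", "w_o", 2))) {
    tgt <- probe[[1]]; nm <- probe[[2]]; k <- probe[[3]]
    pp <- if (tgt == "g") pg else pi_
    pm <- pp
    pp[[nm]][k] <- pp[[nm]][k] + eps
    pm[[nm]][k] <- pm[[nm]][k] - eps
    fd <- if (tgt == "g") {
      (loss_fn(pp, pi_, x) - loss_fn(pm, pi_, x)) / (2 * eps)
    } else {
      (loss_fn(pg, pp, x) - loss_fn(pg, pm, x)) / (2 * eps)
    }
    an <- if (tgt == "g") gb$grads[[nm]][k] else ib$grads[[nm]][k]
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-10), 1e-4)
  }
})
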