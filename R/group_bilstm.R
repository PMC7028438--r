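# Grouped bidirectional LSTM. One *global* Bi-LSTM consumes the elementwise
# sum of all per-lead feature sequences; its hidden state at each time step
# is broadcast (the "global access" connection) into n *intra-group*
# Bi-LSTMs, one per lead, which additionally read their own lead's features.
# Gate layouts (concatenated inputs, in order):
#   global forget:            [C_{t-1}, h_{g,t-1}, sum_i X_{i,t}]
#   global input/cand/output: [h_{g,t-1}, sum_i X_{i,t}]
#   intra  forget:            [C_{t-1}, h_{t-1}, h_{g,t}, X_{i,t}]
#   intra  input/cand/output: [h_{t-1}, h_{g,t}, X_{i,t}]
# The previous cell memory enters the forget gate only (a peephole read
# through a dense block of the forget weight matrix); `full_peephole = TRUE`
# extends the read to the input and output gates. The candidate state always
# excludes the cell memory. All state is zero-initialised.

#' Recurrent module configuration
#'
#' @param hidden_size Hidden/cell dimension of every LSTM.
#' @param share_intra Share intra-group parameters across leads? Sharing
#'   makes the module permutation-equivariant in the leads.
#' @param full_peephole Let the input and output gates also read the
#'   previous cell memory (the forget gate always does).
#' @return A list of class `recurrent_config`.
#' @export
recurrent_config <- function(hidden_size = 64, share_intra = TRUE,
                             full_peephole = FALSE) {
  if (hidden_size < 1) stopf("hidden_size must be at least 1")
  structure(list(hidden_size = hidden_size, share_intra = share_intra,
                 full_peephole = full_peephole),
            class = "recurrent_config")
}

gate_init <- function(d_in_f, d_in_other, d_in_cand, dh) {
  mk <- function(d_in) {
    r <- sqrt(1 / d_in)
    matrix(stats::runif(d_in * dh, -r, r), d_in, dh)
  }
  list(w_f = mk(d_in_f), w_i = mk(d_in_other), w_c = mk(d_in_cand),
       w_o = mk(d_in_other),
       b_f = rep(0, dh), b_i = rep(0, dh), b_c = rep(0, dh), b_o = rep(0, dh))
}

# d: feature dimension per lead; dh: hidden size
global_cell_init <- function(d, dh, full_peephole = FALSE) {
  gate_init(d_in_f = 2 * dh + d,
            d_in_other = (if (full_peephole) 2 * dh else dh) + d,
            d_in_cand = dh + d, dh = dh)
}

intra_cell_init <- function(d, dh, full_peephole = FALSE) {
  gate_init(d_in_f = 3 * dh + d,
            d_in_other = (if (full_peephole) 3 * dh else 2 * dh) + d,
            d_in_cand = 2 * dh + d, dh = dh)
}

rnn_init <- function(d, n_leads, config) {
  dh <- config$hidden_size
  fp <- config$full_peephole
  gl <- list(fwd = global_cell_init(d, dh, fp), bwd = global_cell_init(d, dh, fp))
  if (config$share_intra) {
    intra <- list(fwd = intra_cell_init(d, dh, fp),
                  bwd = intra_cell_init(d, dh, fp))
  } else {
    intra <- lapply(seq_len(n_leads), function(i) {
      list(fwd = intra_cell_init(d, dh, fp), bwd = intra_cell_init(d, dh, fp))
    })
  }
  list(global = gl, intra = intra)
}

# ---- single cell steps (batched: states are [M x D_h] matrices) ----------

#' One step of the global LSTM cell
#'
#' The forget gate reads the previous cell memory, the previous hidden state
#' and the lead-summed features; the input, candidate and output gates read
#' only the previous hidden state and the summed features. State update
#' `C_t = f (*) C_{t-1} + i (*) Ctilde`, output `h = O (*) tanh(C_t)`.
#'
#' @param x_sum Matrix `[M x D]`, elementwise sum of per-lead features at
#'   one time step.
#' @param c_prev,h_prev Matrices `[M x D_h]`, previous cell and hidden
#'   state.
#' @param p Gate parameter list (`w_f`, `w_i`, `w_c`, `w_o`, `b_f`, ...).
#' @param full_peephole See [recurrent_config()].
#' @return List with `c`, `h` (each `[M x D_h]`) and a `cache` for the
#'   backward pass.
#' @export
global_cell_step <- function(x_sum, c_prev, h_prev, p, full_peephole = FALSE) {
  zf <- cbind(c_prev, h_prev, x_sum)
  zo_base <- if (full_peephole) cbind(c_prev, h_prev, x_sum) else cbind(h_prev, x_sum)
  zc <- cbind(h_prev, x_sum)
  f <- sigmoid(zf %*% p$w_f + rep(p$b_f, each = nrow(zf)))
  i <- sigmoid(zo_base %*% p$w_i + rep(p$b_i, each = nrow(zf)))
  cand <- tanh(zc %*% p$w_c + rep(p$b_c, each = nrow(zf)))
  o <- sigmoid(zo_base %*% p$w_o + rep(p$b_o, each = nrow(zf)))
  cc <- f * c_prev + i * cand
  tc <- tanh(cc)
  h <- o * tc
  list(c = cc, h = h,
       cache = list(zf = zf, zio = zo_base, zc = zc, f = f, i = i,
                    cand = cand, o = o, c_prev = c_prev, tc = tc,
                    full_peephole = full_peephole, d = ncol(x_sum),
                    dh = ncol(c_prev)))
}

# dh_up, dc_up: upstream gradients on h and C. Returns gradients on inputs
# (x_sum, c_prev, h_prev) and parameters.
global_cell_backward <- function(dh_up, dc_up, cache, p) {
  dh_dim <- cache$dh
  do_ <- dh_up * cache$tc
  dc <- dc_up + dh_up * cache$o * (1 - cache$tc^2)
  df <- dc * cache$c_prev
  di <- dc * cache$cand
  dcand <- dc * cache$i
  dc_prev <- dc * cache$f
  daf <- df * cache$f * (1 - cache$f)
  dai <- di * cache$i * (1 - cache$i)
  dac <- dcand * (1 - cache$cand^2)
  dao <- do_ * cache$o * (1 - cache$o)
  g <- list(w_f = crossprod(cache$zf, daf), b_f = colSums(daf),
            w_i = crossprod(cache$zio, dai), b_i = colSums(dai),
            w_c = crossprod(cache$zc, dac), b_c = colSums(dac),
            w_o = crossprod(cache$zio, dao), b_o = colSums(dao))
  dzf <- daf %*% t(p$w_f)
  dzio <- dai %*% t(p$w_i) + dao %*% t(p$w_o)
  dzc <- dac %*% t(p$w_c)
  idx <- function(z, a, b) z[, a:b, drop = FALSE]
  # zf = [c_prev | h_prev | x]
  dc_prev <- dc_prev + idx(dzf, 1, dh_dim)
  dh_prev <- idx(dzf, dh_dim + 1, 2 * dh_dim)
  dx <- idx(dzf, 2 * dh_dim + 1, 2 * dh_dim + cache$d)
  if (cache$full_peephole) {
    dc_prev <- dc_prev + idx(dzio, 1, dh_dim)
    dh_prev <- dh_prev + idx(dzio, dh_dim + 1, 2 * dh_dim)
    dx <- dx + idx(dzio, 2 * dh_dim + 1, 2 * dh_dim + cache$d)
  } else {
    dh_prev <- dh_prev + idx(dzio, 1, dh_dim)
    dx <- dx + idx(dzio, dh_dim + 1, dh_dim + cache$d)
  }
  dh_prev <- dh_prev + idx(dzc, 1, dh_dim)
  dx <- dx + idx(dzc, dh_dim + 1, dh_dim + cache$d)
  list(dx = dx, dc_prev = dc_prev, dh_prev = dh_prev, grads = g)
}

#' One step of an intra-group LSTM cell
#'
#' Like [global_cell_step()] but the gates additionally read `h_g`, the
#' same-direction global hidden state at the current time step delivered
#' through the global access connection, and the input is a single lead's
#' feature vector.
#'
#' @param x_it Matrix `[M x D]`, one lead's features at one time step.
#' @param h_g Matrix `[M x D_h]`, global hidden state at the same step.
#' @inheritParams global_cell_step
#' @return List with `c`, `h` and a backward `cache`.
#' @export
intra_cell_step <- function(x_it, h_g, c_prev, h_prev, p,
                            full_peephole = FALSE) {
  zf <- cbind(c_prev, h_prev, h_g, x_it)
  zio <- if (full_peephole) zf else cbind(h_prev, h_g, x_it)
  zc <- cbind(h_prev, h_g, x_it)
  f <- sigmoid(zf %*% p$w_f + rep(p$b_f, each = nrow(zf)))
  i <- sigmoid(zio %*% p$w_i + rep(p$b_i, each = nrow(zf)))
  cand <- tanh(zc %*% p$w_c + rep(p$b_c, each = nrow(zf)))
  o <- sigmoid(zio %*% p$w_o + rep(p$b_o, each = nrow(zf)))
  cc <- f * c_prev + i * cand
  tc <- tanh(cc)
  h <- o * tc
  list(c = cc, h = h,
       cache = list(zf = zf, zio = zio, zc = zc, f = f, i = i, cand = cand,
                    o = o, c_prev = c_prev, tc = tc,
                    full_peephole = full_peephole, d = ncol(x_it),
                    dh = ncol(c_prev)))
}

intra_cell_backward <- function(dh_up, dc_up, cache, p) {
  dh_dim <- cache$dh
  do_ <- dh_up * cache$tc
  dc <- dc_up + dh_up * cache$o * (1 - cache$tc^2)
  df <- dc * cache$c_prev
  di <- dc * cache$cand
  dcand <- dc * cache$i
  dc_prev <- dc * cache$f
  daf <- df * cache$f * (1 - cache$f)
  dai <- di * cache$i * (1 - cache$i)
  dac <- dcand * (1 - cache$cand^2)
  dao <- do_ * cache$o * (1 - cache$o)
  g <- list(w_f = crossprod(cache$zf, daf), b_f = colSums(daf),
            w_i = crossprod(cache$zio, dai), b_i = colSums(dai),
            w_c = crossprod(cache$zc, dac), b_c = colSums(dac),
            w_o = crossprod(cache$zio, dao), b_o = colSums(dao))
  dzf <- daf %*% t(p$w_f)
  dzio <- dai %*% t(p$w_i) + dao %*% t(p$w_o)
  dzc <- dac %*% t(p$w_c)
  idx <- function(z, a, b) z[, a:b, drop = FALSE]
  # zf = [c_prev | h_prev | h_g | x]
  dc_prev <- dc_prev + idx(dzf, 1, dh_dim)
  dh_prev <- idx(dzf, dh_dim + 1, 2 * dh_dim)
  dh_g <- idx(dzf, 2 * dh_dim + 1, 3 * dh_dim)
  dx <- idx(dzf, 3 * dh_dim + 1, 3 * dh_dim + cache$d)
  if (cache$full_peephole) {
    dc_prev <- dc_prev + idx(dzio, 1, dh_dim)
    dh_prev <- dh_prev + idx(dzio, dh_dim + 1, 2 * dh_dim)
    dh_g <- dh_g + idx(dzio, 2 * dh_dim + 1, 3 * dh_dim)
    dx <- dx + idx(dzio, 3 * dh_dim + 1, 3 * dh_dim + cache$d)
  } else {
    dh_prev <- dh_prev + idx(dzio, 1, dh_dim)
    dh_g <- dh_g + idx(dzio, dh_dim + 1, 2 * dh_dim)
    dx <- dx + idx(dzio, 2 * dh_dim + 1, 2 * dh_dim + cache$d)
  }
  dh_prev <- dh_prev + idx(dzc, 1, dh_dim)
  dh_g <- dh_g + idx(dzc, dh_dim + 1, 2 * dh_dim)
  dx <- dx + idx(dzc, 2 * dh_dim + 1, 2 * dh_dim + cache$d)
  list(dx = dx, dh_g = dh_g, dc_prev = dc_prev, dh_prev = dh_prev, grads = g)
}

# ---- full bidirectional pass over a feature sequence ---------------------

intra_params <- function(p_rnn, i, dir, share) {
  if (share) p_rnn$intra[[dir]] else p_rnn$intra[[i]][[dir]]
}

# One direction. xs: list over leads of lists over time of [M x D];
# xsum: list over time of [M x D]; times: processing order of time indices.
run_group_dir <- function(xs, xsum, times, p_rnn, dir, config, m) {
  n <- length(xs)
  t_len <- length(times)
  dh <- config$hidden_size
  fp <- config$full_peephole
  zero <- matrix(0, m, dh)
  hg_seq <- vector("list", t_len)  # indexed by actual time
  hi_seq <- lapply(seq_len(n), function(i) vector("list", t_len))
  gcaches <- vector("list", t_len)
  icaches <- lapply(seq_len(n), function(i) vector("list", t_len))
  cg <- zero; hg <- zero
  ci <- rep(list(zero), n); hi <- rep(list(zero), n)
  pg <- p_rnn$global[[dir]]
  for (t in times) {
    gs <- global_cell_step(xsum[[t]], cg, hg, pg, fp)
    cg <- gs$c; hg <- gs$h
    gcaches[[t]] <- gs$cache
    hg_seq[[t]] <- hg
    for (i in seq_len(n)) {
      ps <- intra_params(p_rnn, i, dir, config$share_intra)
      is <- intra_cell_step(xs[[i]][[t]], hg, ci[[i]], hi[[i]], ps, fp)
      ci[[i]] <- is$c; hi[[i]] <- is$h
      icaches[[i]][[t]] <- is$cache
      hi_seq[[i]][[t]] <- is$h
    }
  }
  list(hg = hg_seq, hi = hi_seq, gcaches = gcaches, icaches = icaches,
       times = times)
}

#' Run the grouped Bi-LSTM over per-lead feature sequences
#'
#' Forward and backward recurrences over `t = 1..T'`; at each step the
#' global cell updates first and its hidden state is delivered to all n
#' same-direction intra cells at the same step.
#'
#' @param feats List of n per-lead feature arrays `[D x T' x M]`, identical
#'   shapes, `n >= 2`.
#' @param p_rnn Parameter structure from the model builder.
#' @param config A [recurrent_config()].
#' @return List with `global` (`fwd`/`bwd` hidden sequences, lists of
#'   `[M x D_h]` matrices indexed by time) and `intra` (n such pairs), plus
#'   caches for the backward pass.
#' @export
run_group <- function(feats, p_rnn, config) {
  n <- length(feats)
  if (n < 2) stopf("at least 2 leads are required")
  dims <- unique(lapply(feats, dim))
  if (length(dims) != 1) stopf("all per-lead feature maps must share one shape")
  d <- dims[[1]][1]; t_len <- dims[[1]][2]; m <- dims[[1]][3]
  xs <- lapply(feats, function(f) {
    lapply(seq_len(t_len), function(t) {
      t(matrix(f[, t, ], nrow = d))
    })
  })
  xsum <- lapply(seq_len(t_len), function(t) Reduce(`+`, lapply(xs, `[[`, t)))
  fwd <- run_group_dir(xs, xsum, seq_len(t_len), p_rnn, "fwd", config, m)
  bwd <- run_group_dir(xs, xsum, rev(seq_len(t_len)), p_rnn, "bwd", config, m)
  list(
    global = list(fwd = fwd$hg, bwd = bwd$hg),
    intra = lapply(seq_len(n), function(i) list(fwd = fwd$hi[[i]],
                                                bwd = bwd$hi[[i]])),
    cache = list(fwd = fwd, bwd = bwd, n = n, d = d, t_len = t_len, m = m)
  )
}

# Backward through one direction. dglobal/dintra: lists over actual time of
# [M x D_h] upstream gradients (NULL allowed). Returns dxs (per lead, per
# time) and parameter gradients.
run_group_dir_backward <- function(dircache, dglobal, dintra, p_rnn, dir,
                                   config) {
  times <- dircache$times
  n <- length(dircache$icaches)
  m <- nrow(dircache$hg[[times[1]]])
  dh_dim <- config$hidden_size
  zero <- matrix(0, m, dh_dim)
  pg <- p_rnn$global[[dir]]
  g_grads <- NULL
  i_grads <- if (config$share_intra) NULL else vector("list", n)
  dxs <- lapply(seq_len(n), function(i) vector("list", length(times)))
  dcg <- zero; dhg_carry <- zero
  dci <- rep(list(zero), n); dhi_carry <- rep(list(zero), n)
  for (t in rev(times)) {
    dhg_here <- (dglobal[[t]] %||% zero) + dhg_carry
    for (i in seq_len(n)) {
      dhi_here <- (dintra[[i]][[t]] %||% zero) + dhi_carry[[i]]
      ps <- intra_params(p_rnn, i, dir, config$share_intra)
      ib <- intra_cell_backward(dhi_here, dci[[i]], dircache$icaches[[i]][[t]], ps)
      dxs[[i]][[t]] <- ib$dx
      dhg_here <- dhg_here + ib$dh_g
      dci[[i]] <- ib$dc_prev
      dhi_carry[[i]] <- ib$dh_prev
      if (config$share_intra) {
        i_grads <- add_params(i_grads, ib$grads)
      } else {
        i_grads[[i]] <- add_params(i_grads[[i]], ib$grads)
      }
    }
    gb <- global_cell_backward(dhg_here, dcg, dircache$gcaches[[t]], pg)
    dcg <- gb$dc_prev
    dhg_carry <- gb$dh_prev
    g_grads <- add_params(g_grads, gb$grads)
    # the summed input feeds every lead's feature gradient
    for (i in seq_len(n)) dxs[[i]][[t]] <- dxs[[i]][[t]] + gb$dx
  }
  list(dxs = dxs, g_grads = g_grads, i_grads = i_grads)
}

# dglobal: list(fwd=, bwd=) of per-time upstream grads; dintra: n such.
run_group_backward <- function(out, dglobal, dintra, p_rnn, config) {
  cache <- out$cache
  n <- cache$n; t_len <- cache$t_len; m <- cache$m; d <- cache$d
  fb <- run_group_dir_backward(cache$fwd, dglobal$fwd,
                               lapply(dintra, `[[`, "fwd"), p_rnn, "fwd", config)
  bb <- run_group_dir_backward(cache$bwd, dglobal$bwd,
                               lapply(dintra, `[[`, "bwd"), p_rnn, "bwd", config)
  dfeats <- lapply(seq_len(n), function(i) {
    arr <- array(0, dim = c(d, t_len, m))
    for (t in seq_len(t_len)) {
      arr[, t, ] <- t(fb$dxs[[i]][[t]] + bb$dxs[[i]][[t]])
    }
    arr
  })
  grads <- list(
    global = list(fwd = fb$g_grads, bwd = bb$g_grads),
    intra = if (config$share_intra) {
      list(fwd = fb$i_grads, bwd = bb$i_grads)
    } else {
      lapply(seq_len(n), function(i) list(fwd = fb$i_grads[[i]],
                                          bwd = bb$i_grads[[i]]))
    }
  )
  list(dfeats = dfeats, grads = grads)
}
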