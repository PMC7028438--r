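# Per-lead residual grouped convolutional encoder. One "group" is one copy
# of this encoder applied to one lead; the number of groups always equals
# the number of input leads. Each group: a strided stem convolution, then
# residual bottleneck blocks (1x1 -> 1x3 -> 1x1, each convolution followed
# by ReLU then batch normalization, in that order), the last block ending in
# four parallel expansion branches (1x3 conv, 1x3 dilated conv rate 2, 1x3
# dilated conv rate 3, average pool + 1x1 projection) whose outputs are
# concatenated along the channel axis.

#' Encoder configuration
#'
#' @param base_channels Channels after the stem convolution.
#' @param branch_channels Channels per expansion branch; the encoder output
#'   dimension is `4 * branch_channels`. Default `base_channels / 2`.
#' @param n_res_blocks Number of residual blocks (the last one carries the
#'   expansion branches).
#' @param stem_kernel,stem_stride Stem convolution size and stride.
#' @param block_strides Per-block temporal strides, length `n_res_blocks`.
#' @param dilation_rates Dilation rates of the two dilated expansion
#'   branches.
#' @param pool_k Average-pool window of the pooling branch.
#' @param share_across_leads Apply identical parameters to every lead?
#' @param order `"relu_bn"` (convolution, ReLU, then batch normalization)
#'   or the conventional `"bn_relu"`.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(base_channels = 32, branch_channels = NULL,
                           n_res_blocks = 3, stem_kernel = 7, stem_stride = 2,
                           block_strides = c(1, 1, 2), dilation_rates = c(2, 3),
                           pool_k = 3, share_across_leads = TRUE,
                           order = c("relu_bn", "bn_relu")) {
  if (n_res_blocks < 1) stopf("n_res_blocks must be at least 1")
  if (length(block_strides) != n_res_blocks) {
    stopf("block_strides must have length n_res_blocks")
  }
  if (any(c(block_strides, stem_stride) < 1)) stopf("strides must be >= 1")
  if (any(dilation_rates < 1)) stopf("dilation rates must be >= 1")
  branch_channels <- branch_channels %||% max(1L, base_channels %/% 2L)
  structure(
    list(base_channels = base_channels, branch_channels = branch_channels,
         n_res_blocks = n_res_blocks, stem_kernel = stem_kernel,
         stem_stride = stem_stride, block_strides = block_strides,
         dilation_rates = dilation_rates, pool_k = pool_k,
         share_across_leads = share_across_leads,
         order = match.arg(order)),
    class = "encoder_config"
  )
}

#' Encoder output length and dimension
#'
#' Closed-form temporal length after the stem and block strides
#' (ceiling division at every strided layer) and the channel dimension of
#' the concatenated expansion branches.
#'
#' @param l_win Input window length (samples).
#' @param config An [encoder_config()].
#' @return List with `t_out` and `d_out`.
#' @export
encoder_out_shape <- function(l_win, config) {
  t <- conv1d_out_len(l_win, config$stem_stride)
  for (s in config$block_strides) t <- conv1d_out_len(t, s)
  list(t_out = t, d_out = 4L * config$branch_channels)
}

# ---- parameter initialisation -------------------------------------------

can_init <- function(c_in, c_out, k) {
  r <- sqrt(1 / (c_in * k))
  list(w = array(stats::runif(c_out * c_in * k, -r, r), dim = c(c_out, c_in, k)),
       b = rep(0, c_out), gamma = rep(1, c_out), beta = rep(0, c_out))
}

proj_init <- function(c_in, c_out, k = 1, stride = 1) {
  r <- sqrt(1 / (c_in * k))
  list(w = array(stats::runif(c_out * c_in * k, -r, r), dim = c(c_out, c_in, k)),
       b = rep(0, c_out))
}

encoder_init <- function(config) {
  base <- config$base_channels
  mid <- max(1L, base %/% 2L)
  bc <- config$branch_channels
  nb <- config$n_res_blocks
  blocks <- vector("list", nb)
  for (bi in seq_len(nb)) {
    s <- config$block_strides[bi]
    if (bi < nb) {
      blk <- list(c1 = can_init(base, mid, 1), c2 = can_init(mid, mid, 3),
                  c3 = can_init(mid, base, 1))
      if (s > 1) blk$sc <- proj_init(base, base)
      blocks[[bi]] <- blk
    } else {
      blocks[[bi]] <- list(
        c1 = can_init(base, mid, 1), c2 = can_init(mid, mid, 3),
        br1 = can_init(mid, bc, 3), br2 = can_init(mid, bc, 3),
        br3 = can_init(mid, bc, 3), brp = can_init(mid, bc, 1),
        sc = proj_init(base, 4L * bc)
      )
    }
  }
  list(stem = can_init(1, base, config$stem_kernel), blocks = blocks)
}

encoder_bn_state <- function(config) {
  base <- config$base_channels
  mid <- max(1L, base %/% 2L)
  bc <- config$branch_channels
  nb <- config$n_res_blocks
  st <- function(ch) list(run_mean = rep(0, ch), run_var = rep(1, ch))
  blocks <- vector("list", nb)
  for (bi in seq_len(nb)) {
    if (bi < nb) {
      blocks[[bi]] <- list(c1 = st(mid), c2 = st(mid), c3 = st(base))
    } else {
      blocks[[bi]] <- list(c1 = st(mid), c2 = st(mid), br1 = st(bc),
                           br2 = st(bc), br3 = st(bc), brp = st(bc))
    }
  }
  list(stem = st(base), blocks = blocks)
}

# ---- conv + activation + normalization unit ------------------------------

can_forward <- function(x, p, st, training, stride = 1, dilation = 1,
                        order = "relu_bn") {
  cv <- conv1d_forward(x, p$w, p$b, stride = stride, dilation = dilation)
  if (order == "relu_bn") {
    r <- relu_forward(cv$out)
    bn <- bn_forward(r$out, p, st, training = training)
    out <- bn$out
  } else {
    bn <- bn_forward(cv$out, p, st, training = training)
    r <- relu_forward(bn$out)
    out <- r$out
  }
  list(out = out, state = bn$state,
       cache = list(cv = cv$cache, r = r$cache, bn = bn$cache, order = order))
}

can_backward <- function(dy, cache) {
  if (cache$order == "relu_bn") {
    bnb <- bn_backward(dy, cache$bn)
    dr <- relu_backward(bnb$dx, cache$r)
    cvb <- conv1d_backward(dr, cache$cv)
  } else {
    dr <- relu_backward(dy, cache$r)
    bnb <- bn_backward(dr, cache$bn)
    cvb <- conv1d_backward(bnb$dx, cache$cv)
  }
  list(dx = cvb$dx,
       grads = list(w = cvb$dw, b = cvb$db, dgamma = bnb$dgamma,
                    dbeta = bnb$dbeta))
}

can_grads <- function(g) list(w = g$w, b = g$b, gamma = g$dgamma, beta = g$dbeta)

# ---- residual bottleneck block ------------------------------------------

res_block_forward <- function(x, p, st, training, stride, order) {
  a1 <- can_forward(x, p$c1, st$c1, training, order = order)
  a2 <- can_forward(a1$out, p$c2, st$c2, training, stride = stride,
                    order = order)
  a3 <- can_forward(a2$out, p$c3, st$c3, training, order = order)
  if (!is.null(p$sc)) {
    sc <- conv1d_forward(x, p$sc$w, p$sc$b, stride = stride)
    short <- sc$out
    sc_cache <- sc$cache
  } else {
    short <- x
    sc_cache <- NULL
  }
  list(out = a3$out + short,
       state = list(c1 = a1$state, c2 = a2$state, c3 = a3$state),
       cache = list(c1 = a1$cache, c2 = a2$cache, c3 = a3$cache,
                    sc = sc_cache))
}

res_block_backward <- function(dy, cache) {
  b3 <- can_backward(dy, cache$c3)
  b2 <- can_backward(b3$dx, cache$c2)
  b1 <- can_backward(b2$dx, cache$c1)
  dx <- b1$dx
  grads <- list(c1 = can_grads(b1$grads), c2 = can_grads(b2$grads),
                c3 = can_grads(b3$grads))
  if (!is.null(cache$sc)) {
    scb <- conv1d_backward(dy, cache$sc)
    dx <- dx + scb$dx
    grads$sc <- list(w = scb$dw, b = scb$db)
  } else {
    dx <- dx + dy
  }
  list(dx = dx, grads = grads)
}

# ---- expansion block (last residual block) -------------------------------

expansion_block_forward <- function(x, p, st, training, stride, config) {
  order <- config$order
  a1 <- can_forward(x, p$c1, st$c1, training, order = order)
  a2 <- can_forward(a1$out, p$c2, st$c2, training, stride = stride,
                    order = order)
  h <- a2$out
  b1 <- can_forward(h, p$br1, st$br1, training, order = order)
  b2 <- can_forward(h, p$br2, st$br2, training,
                    dilation = config$dilation_rates[1], order = order)
  b3 <- can_forward(h, p$br3, st$br3, training,
                    dilation = config$dilation_rates[2], order = order)
  pl <- avgpool_forward(h, k = config$pool_k)
  bp <- can_forward(pl$out, p$brp, st$brp, training, order = order)
  branch_outs <- list(b1$out, b2$out, b3$out, bp$out)
  lens <- vapply(branch_outs, function(o) dim(o)[2], numeric(1))
  if (length(unique(lens)) != 1) stopf("expansion branch length mismatch")
  bc <- dim(b1$out)[1]
  d <- dim(b1$out)
  out <- array(0, dim = c(4 * bc, d[2], d[3]))
  for (i in 1:4) out[(i - 1) * bc + seq_len(bc), , ] <- branch_outs[[i]]
  sc <- conv1d_forward(x, p$sc$w, p$sc$b, stride = stride)
  list(out = out + sc$out,
       state = list(c1 = a1$state, c2 = a2$state, br1 = b1$state,
                    br2 = b2$state, br3 = b3$state, brp = bp$state),
       cache = list(c1 = a1$cache, c2 = a2$cache, br1 = b1$cache,
                    br2 = b2$cache, br3 = b3$cache, pool = pl$cache,
                    brp = bp$cache, sc = sc$cache, bc = bc))
}

expansion_block_backward <- function(dy, cache) {
  bc <- cache$bc
  slice <- function(i) dy[(i - 1) * bc + seq_len(bc), , , drop = FALSE]
  g1 <- can_backward(slice(1), cache$br1)
  g2 <- can_backward(slice(2), cache$br2)
  g3 <- can_backward(slice(3), cache$br3)
  gp <- can_backward(slice(4), cache$brp)
  dpool <- avgpool_backward(gp$dx, cache$pool)
  dh <- g1$dx + g2$dx + g3$dx + dpool
  b2 <- can_backward(dh, cache$c2)
  b1 <- can_backward(b2$dx, cache$c1)
  scb <- conv1d_backward(dy, cache$sc)
  list(dx = b1$dx + scb$dx,
       grads = list(c1 = can_grads(b1$grads), c2 = can_grads(b2$grads),
                    br1 = can_grads(g1$grads), br2 = can_grads(g2$grads),
                    br3 = can_grads(g3$grads), brp = can_grads(gp$grads),
                    sc = list(w = scb$dw, b = scb$db)))
}

# ---- full encoder over one lead -----------------------------------------

encoder_forward <- function(x, p, st, training, config) {
  stem <- can_forward(x, p$stem, st$stem, training,
                      stride = config$stem_stride, order = config$order)
  h <- stem$out
  nb <- config$n_res_blocks
  bcaches <- vector("list", nb)
  bstates <- vector("list", nb)
  for (bi in seq_len(nb)) {
    s <- config$block_strides[bi]
    if (bi < nb) {
      blk <- res_block_forward(h, p$blocks[[bi]], st$blocks[[bi]], training,
                               stride = s, order = config$order)
    } else {
      blk <- expansion_block_forward(h, p$blocks[[bi]], st$blocks[[bi]],
                                     training, stride = s, config = config)
    }
    h <- blk$out
    bcaches[[bi]] <- blk$cache
    bstates[[bi]] <- blk$state
  }
  list(out = h, state = list(stem = stem$state, blocks = bstates),
       cache = list(stem = stem$cache, blocks = bcaches, nb = nb))
}

encoder_backward <- function(dy, cache) {
  nb <- cache$nb
  bgrads <- vector("list", nb)
  dh <- dy
  for (bi in rev(seq_len(nb))) {
    if (bi < nb) {
      bb <- res_block_backward(dh, cache$blocks[[bi]])
    } else {
      bb <- expansion_block_backward(dh, cache$blocks[[bi]])
    }
    dh <- bb$dx
    bgrads[[bi]] <- bb$grads
  }
  sb <- can_backward(dh, cache$stem)
  list(dx = sb$dx, grads = list(stem = can_grads(sb$grads), blocks = bgrads))
}

# ---- all leads -----------------------------------------------------------

# inputs: [M, n_leads, L]; returns per-lead feature arrays [D, T', M].
# With share_across_leads the same parameters are applied to every lead and
# lead gradients are summed.
encode_leads_forward <- function(inputs, p_enc, st_enc, training, config) {
  m <- dim(inputs)[1]; n <- dim(inputs)[2]; l <- dim(inputs)[3]
  if (n < 2) stopf("at least 2 leads are required")
  feats <- vector("list", n)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    x <- array(aperm(inputs[, i, , drop = FALSE], c(2, 3, 1)),
               dim = c(1, l, m))
    pe <- if (config$share_across_leads) p_enc else p_enc[[i]]
    se <- if (config$share_across_leads) st_enc else st_enc[[i]]
    ef <- encoder_forward(x, pe, se, training, config)
    feats[[i]] <- ef$out
    caches[[i]] <- ef$cache
    if (config$share_across_leads) st_enc <- ef$state else st_enc[[i]] <- ef$state
  }
  list(feats = feats, state = st_enc, caches = caches)
}

encode_leads_backward <- function(dfeats, caches, config, n_leads) {
  grads <- NULL
  per_lead <- vector("list", n_leads)
  for (i in seq_len(n_leads)) {
    eb <- encoder_backward(dfeats[[i]], caches[[i]])
    if (config$share_across_leads) {
      grads <- if (is.null(grads)) eb$grads else add_params(grads, eb$grads)
    } else {
      per_lead[[i]] <- eb$grads
    }
  }
  if (config$share_across_leads) grads else per_lead
}
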