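# Nested parameter-list plumbing: all model parameters live in nested named
# lists whose leaves are numeric arrays. Gradient structures mirror the
# parameter structure exactly, so elementwise walks implement accumulation,
# the L2 penalty and the Adam update.

is_leaf <- function(x) is.numeric(x)

# elementwise sum of two parallel structures
add_params <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is_leaf(a)) return(a + b)
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- add_params(a[[nm]], b[[nm]])
  out
}

# zero structure shaped like p
zeros_like <- function(p) {
  if (is.null(p)) return(NULL)
  if (is_leaf(p)) {
    z <- p
    z[] <- 0
    return(z)
  }
  lapply(p, zeros_like)
}

# Walk a structure with leaf names; f(leaf, name) -> leaf.
map_leaves <- function(p, f, name = "") {
  if (is.null(p)) return(NULL)
  if (is_leaf(p)) return(f(p, name))
  out <- p
  nms <- names(p) %||% as.character(seq_along(p))
  for (i in seq_along(p)) out[[i]] <- map_leaves(p[[i]], f, nms[i])
  out
}

# Sum f(leaf, name) over all leaves.
reduce_leaves <- function(p, f, name = "") {
  if (is.null(p)) return(0)
  if (is_leaf(p)) return(f(p, name))
  nms <- names(p) %||% as.character(seq_along(p))
  s <- 0
  for (i in seq_along(p)) s <- s + reduce_leaves(p[[i]], f, nms[i])
  s
}

# Leaves subject to L2 regularization: weight matrices only (convolution,
# dense and gate weights, attention bilinear forms) — not biases, not
# normalization scales/shifts.
is_weight_leaf <- function(name) grepl("^(w|u)", name)

# sum of squared weights
l2_penalty <- function(params) {
  reduce_leaves(params, function(x, nm) if (is_weight_leaf(nm)) sum(x^2) else 0)
}

# gradient of l2_lambda * ||W||^2 added onto an existing grad structure
add_l2_grads <- function(grads, params, l2_lambda) {
  if (l2_lambda == 0) return(grads)
  if (is.null(grads)) return(NULL)
  if (is_leaf(grads)) return(grads)  # handled by the named walk below
  walk <- function(g, p, name) {
    if (is.null(g)) return(NULL)
    if (is_leaf(g)) {
      if (is_weight_leaf(name)) g + 2 * l2_lambda * p else g
    } else {
      keys <- names(g)
      for (i in seq_along(g)) {
        k <- if (!is.null(keys) && nzchar(keys[i])) keys[i] else i
        g[[k]] <- walk(g[[k]], p[[k]], if (is.character(k)) k else "")
      }
      g
    }
  }
  walk(grads, params, "")
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
    if (is_leaf(p)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      return(list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v))
    }
    # gradient structures may order named leaves differently; match by name
    keys <- names(p)
    for (i in seq_along(p)) {
      k <- if (!is.null(keys) && nzchar(keys[i])) keys[i] else i
      r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
      p[[k]] <- r$p
      m[[k]] <- r$m
      v[[k]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}
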