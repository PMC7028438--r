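# Attention pooling over a Bi-LSTM hidden sequence. Per sequence:
#   h_t = forward_t + backward_t                  (per-step sum of directions)
#   F   = forward terminal + backward terminal    (the "final state")
#   s_t = h_t' U F                                (bilinear score)
#   a   = softmax(s)                              (attention distribution)
#   F_nn = sum_t a_t h_t                          (pooled feature)
# The backward direction's terminal step is its own last processed step,
# i.e. time index 1. Every Bi-LSTM in the model owns its own U.

#' Combine the two directions of a Bi-LSTM output
#'
#' @param forward_seq,backward_seq Lists of `[M x D_h]` hidden states
#'   indexed by time, equal length.
#' @return List with `h` (per-step sums, list of `[M x D_h]`) and `f`
#'   (final state, `[M x D_h]`): the forward direction's last step plus the
#'   backward direction's terminal step, which sits at time index 1.
#' @export
combine_directions <- function(forward_seq, backward_seq) {
  t_len <- length(forward_seq)
  if (length(backward_seq) != t_len) stopf("direction sequences differ in length")
  if (t_len < 1) stopf("empty hidden sequence")
  h <- lapply(seq_len(t_len), function(t) forward_seq[[t]] + backward_seq[[t]])
  list(h = h, f = forward_seq[[t_len]] + backward_seq[[1]])
}

#' Bilinear attention scores
#'
#' `s_t = h_t' U F` per sample: a scalar score for each time step, bilinear
#' in the step's hidden state and the final state.
#'
#' @param h List of `[M x D_h]` per-step states.
#' @param u Square weight matrix `[D_h x D_h]`.
#' @param f Final state `[M x D_h]`.
#' @return Matrix `[M x T']` of scores.
#' @export
attention_scores <- function(h, u, f) {
  if (nrow(u) != ncol(u)) stopf("attention weight matrix must be square")
  if (ncol(f) != nrow(u)) stopf("final state dimension does not match U")
  p <- f %*% t(u)  # row m = (U F_m)'
  vapply(h, function(ht) rowSums(ht * p), numeric(nrow(f))) |>
    matrix(nrow = nrow(f))
}

#' Attention distribution
#'
#' Softmax over the per-step scores, computed shift-invariantly
#' (max subtraction), row-wise per sample.
#'
#' @param scores Matrix `[M x T']` of finite scores.
#' @return Matrix `[M x T']`, rows nonnegative and summing to 1.
#' @export
attention_distribution <- function(scores) {
  if (length(scores) == 0) stopf("empty score set")
  if (!all(is.finite(scores))) stopf("scores must be finite")
  softmax_rows(scores)
}

#' Attention-weighted pooling
#'
#' `F_nn = sum_t a_t h_t`: a convex combination of the per-step states.
#'
#' @param a Attention distribution `[M x T']`.
#' @param h List of `T'` per-step states `[M x D_h]`.
#' @return Pooled feature `[M x D_h]`.
#' @export
attention_pool <- function(a, h) {
  if (ncol(a) != length(h)) stopf("attention length does not match sequence")
  out <- matrix(0, nrow(a), ncol(h[[1]]))
  for (t in seq_along(h)) out <- out + a[, t] * h[[t]]
  out
}

# Full attention pooling of one Bi-LSTM output pair, with cache.
attention_forward <- function(forward_seq, backward_seq, u) {
  cd <- combine_directions(forward_seq, backward_seq)
  s <- attention_scores(cd$h, u, cd$f)
  a <- attention_distribution(s)
  fnn <- attention_pool(a, cd$h)
  list(fnn = fnn, a = a,
       cache = list(h = cd$h, f = cd$f, a = a, u = u,
                    t_len = length(cd$h)))
}

# dfnn: [M x D_h]. Returns per-time gradients for both directions and dU.
attention_backward <- function(dfnn, cache) {
  h <- cache$h; f <- cache$f; a <- cache$a; u <- cache$u
  t_len <- cache$t_len
  m <- nrow(f)
  p <- f %*% t(u)
  da <- vapply(h, function(ht) rowSums(dfnn * ht), numeric(m)) |>
    matrix(nrow = m)
  dh <- lapply(seq_len(t_len), function(t) a[, t] * dfnn)
  # softmax backward, row-wise
  ds <- a * (da - rowSums(a * da))
  df <- matrix(0, m, ncol(f))
  du <- matrix(0, nrow(u), ncol(u))
  for (t in seq_len(t_len)) {
    dh[[t]] <- dh[[t]] + ds[, t] * p
    du <- du + crossprod(h[[t]], ds[, t] * f)
    df <- df + (ds[, t] * h[[t]]) %*% u
  }
  dfwd <- dh
  dbwd <- dh
  dfwd[[t_len]] <- dfwd[[t_len]] + df
  dbwd[[1]] <- dbwd[[1]] + df
  list(dfwd = dfwd, dbwd = dbwd, du = du)
}

attention_init <- function(dh) {
  r <- sqrt(1 / dh)
  list(u = matrix(stats::runif(dh * dh, -r, r), dh, dh))
}
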