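#' Dynamic batch-wise class weights
#'
#' For the i-th mini-batch the loss weight of class k is
#' `c_k = 1 - count_k / M + xi`, recomputed every batch: classes rare in
#' the current batch get weights near `1 + xi`, a class filling the whole
#' batch gets exactly `xi`. The additive constant `xi` keeps the weight of
#' a single-class batch away from zero.
#'
#' @param labels Integer vector of M class indices in `1..k_classes`, or a
#'   character vector matched against `class_names`.
#' @param k_classes Number of classes K.
#' @param xi Additive constant, default 0.01.
#' @param class_names Optional class names for character labels.
#' @return Object of class `batch_weights`: list with `c` (length-K weight
#'   vector), `xi`, `m`, `k_classes`.
#' @examples
#' batch_class_weights(rep(1, 32), k_classes = 5)$c[1] # 0.01
#' @export
batch_class_weights <- function(labels, k_classes, xi = 0.01,
                                class_names = NULL) {
  if (length(labels) < 1) stopf("batch must contain at least one label")
  if (is.character(labels)) {
    if (is.null(class_names)) stopf("class_names required for character labels")
    labels <- match(labels, class_names)
    if (anyNA(labels)) stopf("label outside the class set")
  }
  if (any(labels < 1 | labels > k_classes)) stopf("label index outside 1..K")
  m <- length(labels)
  counts <- tabulate(labels, nbins = k_classes)
  structure(
    list(c = 1 - counts / m + xi, xi = xi, m = m, k_classes = k_classes),
    class = "batch_weights"
  )
}

#' Class-weighted cross-entropy with L2 penalty
#'
#' `L = -sum_j c(y_j) log p_j(y_j) + l2_lambda * ||W||^2`, summed over the
#' batch as stated, with the weight `c` indexed by each instance's true
#' class. Probabilities are clamped at 1e-12 before the log.
#'
#' @param pred_probs Matrix `[M x K]`, rows summing to 1 (tolerance 1e-6).
#' @param labels Integer vector of M true class indices.
#' @param weights A [batch_class_weights()] result, or a length-K numeric.
#' @param l2_lambda L2 coefficient (default 0); the penalty uses
#'   `model_weights`.
#' @param model_weights Optional parameter structure whose weight leaves
#'   enter the penalty.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(pred_probs, labels, weights,
                                   l2_lambda = 0, model_weights = NULL) {
  m <- nrow(pred_probs)
  if (length(labels) != m) stopf("labels length must match probability rows")
  if (any(abs(rowSums(pred_probs) - 1) > 1e-6)) {
    stopf("probability rows must sum to 1")
  }
  cw <- if (inherits(weights, "batch_weights")) weights$c else weights
  if (length(cw) != ncol(pred_probs)) stopf("weights length must equal K")
  p_true <- pmax(pred_probs[cbind(seq_len(m), labels)], 1e-12)
  loss <- -sum(cw[labels] * log(p_true))
  if (l2_lambda > 0 && !is.null(model_weights)) {
    loss <- loss + l2_lambda * l2_penalty(model_weights)
  }
  loss
}

#' Joint two-task loss
#'
#' Convex combination `L = task_lambda * L_task1 + (1 - task_lambda) *
#' L_task2` interpolating the coarse and fine diagnosis losses.
#'
#' @param l_task1,l_task2 Scalar task losses.
#' @param task_lambda Interpolation weight in `[0, 1]`; default 0.2 (the
#'   setting favouring the fine-grained task).
#' @return Scalar.
#' @export
joint_loss <- function(l_task1, l_task2, task_lambda = 0.2) {
  if (task_lambda < 0 || task_lambda > 1) {
    stopf("task_lambda must lie in [0, 1]")
  }
  task_lambda * l_task1 + (1 - task_lambda) * l_task2
}

#' Loss configuration
#'
#' @param xi Additive constant of the dynamic class weights (> 0).
#' @param l2_lambda L2 regularization coefficient (>= 0).
#' @param task_lambda Task interpolation weight in `[0, 1]`.
#' @param dynamic_weights Use batch-wise dynamic class weights? `FALSE`
#'   forces uniform weights (the ablation switch).
#' @return List of class `loss_config`.
#' @export
loss_config <- function(xi = 0.01, l2_lambda = 0.01, task_lambda = 0.2,
                        dynamic_weights = TRUE) {
  if (xi <= 0) stopf("xi must be positive")
  if (l2_lambda < 0) stopf("l2_lambda must be nonnegative")
  if (task_lambda < 0 || task_lambda > 1) stopf("task_lambda must lie in [0, 1]")
  structure(list(xi = xi, l2_lambda = l2_lambda, task_lambda = task_lambda,
                 dynamic_weights = dynamic_weights),
            class = "loss_config")
}

# Gradient of the weighted cross-entropy (sum over batch, no L2 term) with
# respect to the pre-softmax logits: c(y_j) * (p_j - onehot_j).
wce_logit_grad <- function(pred_probs, labels, cw) {
  m <- nrow(pred_probs)
  g <- pred_probs
  g[cbind(seq_len(m), labels)] <- g[cbind(seq_len(m), labels)] - 1
  g * cw[labels]
}
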