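#' Model configuration
#'
#' Assembles the full classifier configuration: one convolutional encoder
#' group per lead, the grouped Bi-LSTM (one global + n intra), one attention
#' pooling per Bi-LSTM, and two softmax heads over the concatenation of all
#' n+1 pooled features — a coarse 5-class head and a fine 15-class head
#' trained jointly.
#'
#' @param n_leads Number of input leads (>= 2).
#' @param l_win Model input window length in samples (default 1900).
#' @param window_policy Windowing policy, see [window_record()].
#' @param encoder An [encoder_config()].
#' @param recurrent A [recurrent_config()].
#' @param loss A [loss_config()].
#' @param k1,k2 Head sizes; the diagnostic taxonomy fixes 5 and 15.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size M.
#' @param seed Integer seed controlling initialisation and batching.
#' @return List of class `model_config`.
#' @export
model_config <- function(n_leads = 12, l_win = 1900,
                         window_policy = "decimate",
                         encoder = encoder_config(),
                         recurrent = recurrent_config(),
                         loss = loss_config(),
                         k1 = 5, k2 = 15,
                         lr = 1e-3, epochs = 20, batch_size = 32,
                         seed = 1) {
  if (n_leads < 2) stopf("n_leads must be at least 2")
  if (k1 != length(task1_classes()) || k2 != length(task2_classes())) {
    stopf("head sizes must match the diagnostic taxonomy (5 and 15 classes)")
  }
  structure(
    list(n_leads = n_leads, l_win = l_win, window_policy = window_policy,
         encoder = encoder, recurrent = recurrent, loss = loss,
         k1 = k1, k2 = k2, lr = lr, epochs = epochs,
         batch_size = batch_size, seed = seed),
    class = "model_config"
  )
}

#' Build an untrained model
#'
#' Initialises all parameters (seeded small-uniform) for the configured
#' lead count: `n_leads` encoder groups (shared or per-lead parameters),
#' one global and `n_leads` intra-group Bi-LSTMs, `n_leads + 1` attention
#' instances, and the two heads over the `(n_leads + 1) * hidden_size`
#' concatenated representation.
#'
#' @param config A [model_config()].
#' @return Object of class `leadwise_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  n <- config$n_leads
  shape <- encoder_out_shape(config$l_win, config$encoder)
  d <- shape$d_out
  dh <- config$recurrent$hidden_size
  params <- with_seed(config$seed, {
    enc <- if (config$encoder$share_across_leads) {
      encoder_init(config$encoder)
    } else {
      lapply(seq_len(n), function(i) encoder_init(config$encoder))
    }
    list(
      enc = enc,
      rnn = rnn_init(d, n, config$recurrent),
      att = lapply(seq_len(n + 1), function(i) attention_init(dh)),
      head1 = {
        r <- sqrt(1 / ((n + 1) * dh))
        list(w = matrix(stats::runif((n + 1) * dh * config$k1, -r, r),
                        (n + 1) * dh, config$k1),
             b = rep(0, config$k1))
      },
      head2 = {
        r <- sqrt(1 / ((n + 1) * dh))
        list(w = matrix(stats::runif((n + 1) * dh * config$k2, -r, r),
                        (n + 1) * dh, config$k2),
             b = rep(0, config$k2))
      }
    )
  })
  bn_state <- if (config$encoder$share_across_leads) {
    encoder_bn_state(config$encoder)
  } else {
    lapply(seq_len(n), function(i) encoder_bn_state(config$encoder))
  }
  structure(
    list(params = params, bn_state = bn_state, config = config,
         t_prime = shape$t_out, d_feat = d),
    class = "leadwise_model"
  )
}

#' @export
print.leadwise_model <- function(x, ...) {
  cfg <- x$config
  n_par <- reduce_leaves(x$params, function(p, nm) length(p))
  cat(sprintf(paste0(
    "<leadwise_model: %d leads, window %d -> T'=%d x D=%d, hidden %d,\n",
    "  %d encoder groups, 1 global + %d intra Bi-LSTMs, %d attention instances,\n",
    "  heads %d/%d classes, %s parameters>\n"),
    cfg$n_leads, cfg$l_win, x$t_prime, x$d_feat,
    cfg$recurrent$hidden_size, cfg$n_leads, cfg$n_leads, cfg$n_leads + 1,
    cfg$k1, cfg$k2, format(n_par, big.mark = ",")))
  invisible(x)
}

#' Count of architectural components
#'
#' @param model A [build_model()] result.
#' @return Tibble with one row per component type and its count.
#' @export
model_component_counts <- function(model) {
  n <- model$config$n_leads
  tibble::tibble(
    component = c("encoder_groups", "global_bilstm", "intra_bilstm",
                  "attention_instances", "head1_classes", "head2_classes"),
    count = c(n, 1L, n, n + 1L, model$config$k1, model$config$k2)
  )
}

# ---- forward pass ---------------------------------------------------------

# inputs: [M x n x L]; returns probabilities, attention maps and (when
# requested) all caches needed for the backward pass.
model_forward <- function(model, inputs, training = FALSE,
                          keep_cache = FALSE) {
  cfg <- model$config
  din <- dim(inputs)
  if (din[2] != cfg$n_leads) {
    stopf("input has %d leads but the model expects %d", din[2], cfg$n_leads)
  }
  if (din[3] != cfg$l_win) {
    stopf("input window length %d does not match the configured %d",
          din[3], cfg$l_win)
  }
  enc <- encode_leads_forward(inputs, model$params$enc, model$bn_state,
                              training, cfg$encoder)
  gb <- run_group(enc$feats, model$params$rnn, cfg$recurrent)
  n <- cfg$n_leads
  seqs <- c(list(gb$global), gb$intra)
  atts <- lapply(seq_len(n + 1), function(i) {
    attention_forward(seqs[[i]]$fwd, seqs[[i]]$bwd, model$params$att[[i]]$u)
  })
  z <- do.call(cbind, lapply(atts, `[[`, "fnn"))
  h1 <- dense_forward(z, model$params$head1$w, model$params$head1$b)
  h2 <- dense_forward(z, model$params$head2$w, model$params$head2$b)
  probs1 <- softmax_rows(h1$out)
  probs2 <- softmax_rows(h2$out)
  out <- list(
    probs1 = probs1, probs2 = probs2,
    attention = lapply(atts, `[[`, "a"),
    bn_state = enc$state
  )
  if (keep_cache) {
    out$cache <- list(enc = enc$caches, gb = gb,
                      att = lapply(atts, `[[`, "cache"),
                      h1 = h1$cache, h2 = h2$cache, n = n)
  }
  out
}

# dlogits1/dlogits2: [M x K] gradients on the two heads' pre-softmax logits.
model_backward <- function(model, fwd, dlogits1, dlogits2) {
  cfg <- model$config
  n <- fwd$cache$n
  dh <- cfg$recurrent$hidden_size
  b1 <- dense_backward(dlogits1, fwd$cache$h1)
  b2 <- dense_backward(dlogits2, fwd$cache$h2)
  dz <- b1$dz + b2$dz
  t_len <- model$t_prime
  datt <- vector("list", n + 1)
  du <- vector("list", n + 1)
  for (i in seq_len(n + 1)) {
    dfnn <- dz[, (i - 1) * dh + seq_len(dh), drop = FALSE]
    ab <- attention_backward(dfnn, fwd$cache$att[[i]])
    datt[[i]] <- ab
    du[[i]] <- list(u = ab$du)
  }
  dglobal <- list(fwd = datt[[1]]$dfwd, bwd = datt[[1]]$dbwd)
  dintra <- lapply(seq_len(n), function(i) {
    list(fwd = datt[[i + 1]]$dfwd, bwd = datt[[i + 1]]$dbwd)
  })
  rb <- run_group_backward(fwd$cache$gb, dglobal, dintra,
                           model$params$rnn, cfg$recurrent)
  enc_grads <- encode_leads_backward(rb$dfeats, fwd$cache$enc, cfg$encoder, n)
  list(enc = enc_grads, rnn = rb$grads, att = du,
       head1 = list(w = b1$dw, b = b1$db),
       head2 = list(w = b2$dw, b = b2$db))
}

# ---- training -------------------------------------------------------------

batch_to_indices <- function(batch) {
  list(y1 = match(batch$labels1, task1_classes()),
       y2 = match(batch$labels2, task2_classes()))
}

#' Train a model with Adam on the joint two-task loss
#'
#' Minimises `task_lambda * L_task1 + (1 - task_lambda) * L_task2 +
#' l2_lambda * ||W||^2` where each task loss is the batch-summed
#' cross-entropy weighted by that task's dynamic batch class weights
#' (uniform weights when `loss$dynamic_weights` is `FALSE`). Fully seeded:
#' batch order derives from the model seed and the epoch index.
#'
#' @param model A [build_model()] result.
#' @param dataset An [ecg_dataset()].
#' @param epochs,lr Override the config values.
#' @param verbose Print per-epoch progress?
#' @return Object of class `leadwise_fit`: the trained model plus a tibble
#'   `history` (epoch, iter, loss1, loss2, joint, accuracy1, accuracy2).
#' @export
train_model <- function(model, dataset, epochs = NULL, lr = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "leadwise_model"), inherits(dataset, "ecg_dataset"))
  if (length(dataset$records) == 0) stopf("dataset is empty")
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  lr <- lr %||% cfg$lr
  lcf <- cfg$loss
  params <- model$params
  bn_state <- model$bn_state
  opt <- adam_init(params)
  hist <- list()
  iter <- 0
  for (ep in seq_len(epochs)) {
    batches <- make_batches(dataset, m = cfg$batch_size, l_win = cfg$l_win,
                            policy = cfg$window_policy, shuffle = TRUE,
                            seed = derive_seed(cfg$seed, 100000 + ep))
    for (b in batches) {
      iter <- iter + 1
      y <- batch_to_indices(b)
      mdl <- model
      mdl$params <- params
      mdl$bn_state <- bn_state
      fwd <- model_forward(mdl, b$inputs, training = TRUE, keep_cache = TRUE)
      bn_state <- fwd$bn_state
      cw1 <- if (lcf$dynamic_weights) {
        batch_class_weights(y$y1, cfg$k1, xi = lcf$xi)$c
      } else rep(1, cfg$k1)
      cw2 <- if (lcf$dynamic_weights) {
        batch_class_weights(y$y2, cfg$k2, xi = lcf$xi)$c
      } else rep(1, cfg$k2)
      l1 <- weighted_cross_entropy(fwd$probs1, y$y1, cw1)
      l2 <- weighted_cross_entropy(fwd$probs2, y$y2, cw2)
      reg <- lcf$l2_lambda * l2_penalty(params)
      jl <- joint_loss(l1, l2, lcf$task_lambda) + reg
      if (!is.finite(jl)) {
        stopf("training diverged (non-finite loss) at iteration %d", iter)
      }
      dl1 <- lcf$task_lambda * wce_logit_grad(fwd$probs1, y$y1, cw1)
      dl2 <- (1 - lcf$task_lambda) * wce_logit_grad(fwd$probs2, y$y2, cw2)
      grads <- model_backward(mdl, fwd, dl1, dl2)
      grads <- add_l2_grads(grads, params, lcf$l2_lambda)
      st <- adam_step(params, grads, opt, lr = lr)
      params <- st$params
      opt <- st$state
      hist[[iter]] <- tibble::tibble(
        epoch = ep, iter = iter, loss1 = l1, loss2 = l2, joint = jl,
        accuracy1 = mean(max.col(fwd$probs1) == y$y1),
        accuracy2 = mean(max.col(fwd$probs2) == y$y2)
      )
    }
    if (verbose) {
      last <- hist[[iter]]
      message(sprintf("epoch %d: joint %.4f acc1 %.3f acc2 %.3f",
                      ep, last$joint, last$accuracy1, last$accuracy2))
    }
  }
  model$params <- params
  model$bn_state <- bn_state
  structure(list(model = model, history = dplyr::bind_rows(hist)),
            class = "leadwise_fit")
}

#' @export
print.leadwise_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<leadwise_fit: %d iterations, final joint loss %.4f, final batch accuracy %.3f/%.3f>\n",
              nrow(x$history), last$joint, last$accuracy1, last$accuracy2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.leadwise_fit <- function(x, ...) x$history

#' @export
glance.leadwise_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(iterations = nrow(x$history), final_joint = last$joint,
                 final_loss1 = last$loss1, final_loss2 = last$loss2,
                 final_accuracy1 = last$accuracy1,
                 final_accuracy2 = last$accuracy2)
}

#' Plot a training history
#' @param object A `leadwise_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.leadwise_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("loss1", "loss2", "joint"),
                            names_to = "loss", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iter, y = .data$value,
                                   colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "batch loss", colour = NULL) +
    ggplot2::theme_minimal()
}

# ---- prediction and evaluation --------------------------------------------

#' Predict labels for a dataset
#'
#' Runs the model in evaluation mode (running normalization statistics, no
#' stochasticity) and returns one row per record.
#'
#' @param fit A `leadwise_fit` or `leadwise_model`.
#' @param dataset An [ecg_dataset()].
#' @param batch_size Evaluation batch size.
#' @param dump_attention Also return per-step attention weights?
#' @return Tibble with `record_id`, truth and predicted labels for both
#'   tasks and the predicted-class probabilities. With
#'   `dump_attention = TRUE`, a list with `predictions` and a long tibble
#'   `attention` (record_id, instance, step, weight).
#' @export
predict_labels <- function(fit, dataset, batch_size = 64,
                           dump_attention = FALSE) {
  model <- if (inherits(fit, "leadwise_fit")) fit$model else fit
  cfg <- model$config
  ds <- if (!identical(dataset$lead_names, .model_leads(model, dataset))) {
    select_leads(dataset, .model_leads(model, dataset))
  } else dataset
  batches <- make_batches(ds, m = batch_size, l_win = cfg$l_win,
                          policy = cfg$window_policy, shuffle = FALSE)
  preds <- list()
  att_rows <- list()
  for (bi in seq_along(batches)) {
    b <- batches[[bi]]
    fwd <- model_forward(model, b$inputs, training = FALSE)
    preds[[bi]] <- tibble::tibble(
      record_id = b$record_ids,
      truth1 = b$labels1, truth2 = b$labels2,
      pred1 = task1_classes()[max.col(fwd$probs1)],
      pred2 = task2_classes()[max.col(fwd$probs2)],
      prob1 = apply(fwd$probs1, 1, max),
      prob2 = apply(fwd$probs2, 1, max)
    )
    if (dump_attention) {
      inst <- c("global", ds$lead_names)
      att_rows[[bi]] <- purrr::imap_dfr(fwd$attention, function(a, i) {
        tibble::tibble(
          record_id = rep(b$record_ids, ncol(a)),
          instance = inst[i],
          step = rep(seq_len(ncol(a)), each = nrow(a)),
          weight = as.vector(a)
        )
      })
    }
  }
  predictions <- dplyr::bind_rows(preds)
  if (dump_attention) {
    list(predictions = predictions, attention = dplyr::bind_rows(att_rows))
  } else {
    predictions
  }
}

.model_leads <- function(model, dataset) {
  if (length(dataset$lead_names) == model$config$n_leads) {
    dataset$lead_names
  } else {
    stopf("dataset has %d leads but the model expects %d",
          length(dataset$lead_names), model$config$n_leads)
  }
}

# per-class precision/recall/F1 from a confusion matrix (rows = truth)
.class_metrics <- function(cm) {
  classes <- rownames(cm)
  support <- rowSums(cm)
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, NA_real_)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall),
               ifelse(is.na(precision) | is.na(recall), NA_real_, 0))
  # a class absent from both truth and prediction is undefined, not zero
  absent <- support == 0 & pred_tot == 0
  precision[absent] <- NA_real_
  recall[absent] <- NA_real_
  f1[absent] <- NA_real_
  tibble::tibble(class = classes, support = as.integer(unname(support)),
                 precision = unname(precision), recall = unname(recall),
                 f1 = unname(f1))
}

.aggregate_metrics <- function(per_class, cm) {
  acc <- sum(diag(cm)) / sum(cm)
  ok <- !is.na(per_class$f1)
  w <- per_class$support[ok] / sum(per_class$support[ok])
  tibble::tibble(
    accuracy = acc,
    precision_macro = mean(per_class$precision[ok], na.rm = TRUE),
    recall_macro = mean(per_class$recall[ok], na.rm = TRUE),
    f1_macro = mean(per_class$f1[ok], na.rm = TRUE),
    precision_weighted = sum(w * per_class$precision[ok], na.rm = TRUE),
    recall_weighted = sum(w * per_class$recall[ok], na.rm = TRUE),
    f1_weighted = sum(w * per_class$f1[ok], na.rm = TRUE)
  )
}

#' Evaluate predictions against both label levels
#'
#' Computes per-class and aggregate (macro and support-weighted) precision,
#' recall and F1 for both tasks, the fine-grained confusion matrix in
#' counts and as row-normalized percentages. Classes absent from both truth
#' and prediction are reported as `NA` and excluded from the macro
#' averages.
#'
#' @param fit A `leadwise_fit` or `leadwise_model`.
#' @param dataset An [ecg_dataset()].
#' @param ... Passed to [predict_labels()].
#' @return Object of class `eval_report`.
#' @export
evaluate_model <- function(fit, dataset, ...) {
  preds <- predict_labels(fit, dataset, ...)
  eval_report(preds)
}

#' Build an evaluation report from a prediction table
#'
#' @param preds Tibble with `truth1`, `truth2`, `pred1`, `pred2`.
#' @return Object of class `eval_report`.
#' @export
eval_report <- function(preds) {
  cm2 <- table(factor(preds$truth2, levels = task2_classes()),
               factor(preds$pred2, levels = task2_classes()))
  cm1 <- table(factor(preds$truth1, levels = task1_classes()),
               factor(preds$pred1, levels = task1_classes()))
  cm2 <- unclass(cm2); cm1 <- unclass(cm1)
  per2 <- .class_metrics(cm2)
  per1 <- .class_metrics(cm1)
  norm2 <- sweep(cm2, 1, pmax(rowSums(cm2), 1), "/") * 100
  structure(
    list(task1 = list(per_class = per1, aggregate = .aggregate_metrics(per1, cm1),
                      confusion = cm1),
         task2 = list(per_class = per2, aggregate = .aggregate_metrics(per2, cm2),
                      confusion = cm2, confusion_pct = norm2),
         predictions = preds),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  a <- x$task2$aggregate
  cat(sprintf("<eval_report: fine task accuracy %.3f, macro F1 %.3f, weighted F1 %.3f>\n",
              a$accuracy, a$f1_macro, a$f1_weighted))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, task = c("task2", "task1"), ...) {
  task <- match.arg(task)
  x[[task]]$per_class
}

#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(
    dplyr::rename_with(x$task1$aggregate, ~ paste0("task1_", .x)),
    dplyr::rename_with(x$task2$aggregate, ~ paste0("task2_", .x))
  )
}

#' Plot the row-normalized fine-grained confusion matrix
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$task2$confusion_pct))
  names(df) <- c("truth", "predicted", "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(fill = "% of truth row") +
    ggplot2::theme_minimal()
}

# ---- splits and lead ablation --------------------------------------------

#' Stratified train/validation/test split
#'
#' Splits record ids by fine-grained label, deterministically under `seed`;
#' the three parts are disjoint.
#'
#' @param dataset An [ecg_dataset()].
#' @param props Length-3 proportions summing to 1.
#' @param seed Integer seed.
#' @return List of three [ecg_dataset()]s: `train`, `validation`, `test`.
#' @export
split_dataset <- function(dataset, props = c(0.8, 0.1, 0.1), seed) {
  stopifnot(abs(sum(props) - 1) < 1e-8)
  n <- length(dataset$records)
  lab <- dataset$manifest$task2
  assign_part <- with_seed(seed, {
    part <- integer(n)
    for (cl in unique(lab)) {
      idx <- sample(which(lab == cl))
      k <- length(idx)
      n1 <- round(props[1] * k)
      n2 <- round(props[2] * k)
      part[idx] <- c(rep(1, n1), rep(2, min(n2, k - n1)),
                     rep(3, max(0, k - n1 - n2)))[seq_len(k)]
    }
    part
  })
  subset_ds <- function(which_part) {
    idx <- which(assign_part == which_part)
    if (length(idx) == 0) return(NULL)
    ecg_dataset(dataset$records[idx], manifest = dataset$manifest[idx, ])
  }
  list(train = subset_ds(1), validation = subset_ds(2), test = subset_ds(3))
}

#' Train and evaluate the same records under several lead subsets
#'
#' Identical records, split and seeds across presets; only the lead
#' selection differs, exercising the architecture's lead-count flexibility
#' (the group count follows the input).
#'
#' @param dataset A 12-lead [ecg_dataset()].
#' @param presets Named list of lead-name vectors; see [lead_presets()].
#' @param config Base [model_config()]; `n_leads` is overridden per preset.
#' @param split_seed Seed for the shared record split.
#' @return Tibble with one row per preset: preset name, lead count,
#'   `report` (list column of `eval_report`s) and aggregate fine-task
#'   metrics.
#' @export
lead_ablation <- function(dataset, presets = lead_presets(), config,
                          split_seed = 1) {
  missing_leads <- setdiff(unique(unlist(presets)), dataset$lead_names)
  if (length(missing_leads) > 0) {
    stopf("preset lead(s) missing from data: %s",
          paste(missing_leads, collapse = ", "))
  }
  if (any(lengths(presets) < 2)) stopf("presets must have at least 2 leads")
  parts <- split_dataset(dataset, seed = split_seed)
  rows <- purrr::imap(presets, function(leads, nm) {
    cfg <- config
    cfg$n_leads <- length(leads)
    train_ds <- select_leads(parts$train, leads)
    test_ds <- select_leads(parts$test %||% parts$train, leads)
    fit <- train_model(build_model(cfg), train_ds)
    rep <- evaluate_model(fit, test_ds)
    tibble::tibble(preset = nm, n_leads = length(leads),
                   record_ids = list(sort(test_ds$manifest$record_id)),
                   report = list(rep),
                   accuracy = rep$task2$aggregate$accuracy,
                   f1_macro = rep$task2$aggregate$f1_macro)
  })
  dplyr::bind_rows(rows)
}

# ---- checkpointing --------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive of all parameters, normalization
#' statistics and the configuration.
#'
#' @param fit A `leadwise_fit` or `leadwise_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored object (load).
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
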