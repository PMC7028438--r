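test_that("model construction is deterministic and counts components correctly", {
  cfg <- tiny_config(n_leads = 12, seed = 8)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)

  counts <- model_component_counts(m1)
  expect_equal(counts$count[counts$component == "encoder_groups"], 12)
  expect_equal(counts$count[counts$component == "global_bilstm"], 1)
  expect_equal(counts$count[counts$component == "intra_bilstm"], 12)
  expect_equal(counts$count[counts$component == "attention_instances"], 13)
  expect_equal(ncol(m1$params$head1$w), 5)
  expect_equal(ncol(m1$params$head2$w), 15)
  expect_error(model_config(n_leads = 1), "at least 2")
  expect_error(model_config(k1 = 4), "taxonomy")
})

test_that("forward pass emits normalized distributions and per-instance attention", {
  ds <- tiny_dataset(4, seed = 17, duration = 3, fs = 80)
  cfg <- tiny_config(n_leads = 12, l_win = 48, hidden = 6,
                     base_channels = 4, batch_size = 4)
  m <- build_model(cfg)
  b <- make_batches(ds, m = 4, l_win = 48, seed = 2)[[1]]
  fwd <- leadwise:::model_forward(m, b$inputs, training = FALSE)
  expect_equal(rowSums(fwd$probs1), rep(1, 4), tolerance = 1e-6)
  expect_equal(rowSums(fwd$probs2), rep(1, 4), tolerance = 1e-6)
  expect_length(fwd$attention, 13)
  expect_equal(dim(fwd$attention[[1]]), c(4, m$t_prime))

  # evaluation mode is batch-size independent (running statistics)
  single <- b$inputs[2, , , drop = FALSE]
  fwd1 <- leadwise:::model_forward(m, single, training = FALSE)
  expect_equal(as.vector(fwd1$probs2), fwd$probs2[2, ], tolerance = 1e-10)

  wrong <- array(0, dim = c(2, 5, 48))
  expect_error(leadwise:::model_forward(m, wrong, training = FALSE), "leads")
})

test_that("the coarse-only endpoint silences fine-head gradients", {
  ds <- tiny_dataset(4, seed = 19, duration = 3, fs = 80)
  cfg <- tiny_config(n_leads = 12, l_win = 32, hidden = 4, base_channels = 4,
                     batch_size = 4)
  m <- build_model(cfg)
  b <- make_batches(ds, m = 4, l_win = 32, seed = 2)[[1]]
  y <- leadwise:::batch_to_indices(b)
  fwd <- leadwise:::model_forward(m, b$inputs, training = TRUE,
                                  keep_cache = TRUE)
  lam <- 1  # task-lambda endpoint: only the coarse task contributes
  dl1 <- lam * leadwise:::wce_logit_grad(fwd$probs1, y$y1,
                                         batch_class_weights(y$y1, 5)$c)
  dl2 <- (1 - lam) * leadwise:::wce_logit_grad(fwd$probs2, y$y2,
                                               batch_class_weights(y$y2, 15)$c)
  g <- leadwise:::model_backward(m, fwd, dl1, dl2)
  expect_true(all(g$head2$w == 0))
  expect_true(all(g$head2$b == 0))
  expect_gt(max(abs(g$head1$w)), 0)
})

test_that("training is seeded-reproducible and checkpoints round-trip", {
  ds <- tiny_dataset(12, seed = 23, duration = 3, fs = 80)
  cfg <- tiny_config(n_leads = 12, l_win = 32, hidden = 4, base_channels = 4,
                     epochs = 2, batch_size = 6, seed = 5)
  f1 <- train_model(build_model(cfg), ds)
  f2 <- train_model(build_model(cfg), ds)
  expect_equal(f1$history$joint, f2$history$joint, tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(f1, path)
  restored <- load_checkpoint(path)
  p1 <- predict_labels(f1, ds)
  p2 <- predict_labels(restored, ds)
  expect_identical(p1, p2)

  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(nrow(glance(f1)), 1)
  expect_s3_class(autoplot(f1), "ggplot")
})

test_that("evaluation metrics match hand-computed confusion arithmetic", {
  # 2-class toy confusion [[8,2],[1,9]]
  cm <- matrix(c(8, 1, 2, 9), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  pc <- leadwise:::.class_metrics(cm)
  expect_equal(pc$precision[1], 8 / 9)
  expect_equal(pc$recall[1], 0.8)
  expect_equal(pc$f1[1], 16 / 19)

  # perfect predictions
  preds <- tibble::tibble(truth1 = c("N", "MI"), truth2 = c("N", "AMI"),
                          pred1 = c("N", "MI"), pred2 = c("N", "AMI"))
  rep <- eval_report(preds)
  expect_equal(rep$task2$aggregate$accuracy, 1)
  expect_equal(rep$task2$aggregate$f1_macro, 1)
  expect_true(all(diag(rep$task2$confusion)[c("N", "AMI")] == 1))

  # degenerate predictor: everything called N
  preds2 <- tibble::tibble(truth1 = c("N", "AR", "MI"),
                           truth2 = c("N", "SA", "AMI"),
                           pred1 = rep("N", 3), pred2 = rep("N", 3))
  rep2 <- eval_report(preds2)
  pc2 <- rep2$task2$per_class
  expect_equal(pc2$recall[pc2$class == "N"], 1)
  expect_equal(pc2$recall[pc2$class == "SA"], 0)
  expect_equal(pc2$recall[pc2$class == "AMI"], 0)
  # classes absent from truth and prediction are undefined, not zero
  expect_true(is.na(pc2$f1[pc2$class == "HB"]))
  # normalized confusion rows with support sum to 100
  sums <- rowSums(rep2$task2$confusion_pct)
  expect_equal(unname(sums[c("N", "SA", "AMI")]), rep(100, 3))

  expect_s3_class(glance(rep2), "tbl_df")
  expect_s3_class(autoplot(rep2), "ggplot")
})

test_that("stratified splits are disjoint and seeded", {
  ds <- tiny_dataset(40, seed = 29, duration = 3, fs = 50)
  sp <- split_dataset(ds, seed = 4)
  ids <- lapply(sp, function(d) if (is.null(d)) character(0) else d$manifest$record_id)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$train, ids$validation), 0)
  expect_setequal(unlist(ids), ds$manifest$record_id)
  sp2 <- split_dataset(ds, seed = 4)
  expect_identical(sp$train$manifest$record_id, sp2$train$manifest$record_id)
})
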