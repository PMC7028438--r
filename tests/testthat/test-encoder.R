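# Encoder internals are exercised directly through the package's
# (unexported) layer functions; gradient correctness is pinned by the
# finite-difference test in test-gradients.R.

cv <- leadwise:::conv1d_forward
bn <- leadwise:::bn_forward

test_that("conv-relu-norm unit handles the zero case and the relu-then-norm order", {
  x <- array(rnorm(2 * 10 * 3), dim = c(2, 10, 3))
  p <- leadwise:::can_init(2, 4, 3)
  p$w[] <- 0
  st <- list(run_mean = rep(0, 4), run_var = rep(1, 4))
  out <- leadwise:::can_forward(x, p, st, training = TRUE)
  expect_true(all(out$out == 0))  # zero conv -> zero relu -> zero-mean BN

  # 1x1 identity kernel, evaluation mode with unit statistics: y = relu(x)
  p1 <- leadwise:::can_init(2, 2, 1)
  p1$w[] <- 0
  p1$w[1, 1, 1] <- 1
  p1$w[2, 2, 1] <- 1
  st1 <- list(run_mean = rep(0, 2), run_var = rep(1 - 1e-5, 2))
  out1 <- leadwise:::can_forward(x, p1, st1, training = FALSE)
  expect_equal(out1$out, pmax(x, 0), tolerance = 1e-7)
})

test_that("dilated convolution has receptive field (k-1)*d + 1", {
  # impulse response support of a dilation-2, width-3 kernel spans 5 samples
  x <- array(0, dim = c(1, 21, 1))
  x[1, 11, 1] <- 1
  w <- array(1, dim = c(1, 1, 3))
  y <- cv(x, w, b = 0, stride = 1, dilation = 2)$out
  expect_equal(which(y[1, , 1] != 0), c(9L, 11L, 13L))
  expect_equal(diff(range(which(y[1, , 1] != 0))) + 1, (3 - 1) * 2 + 1)
})

test_that("residual blocks reduce to the shortcut at zero weights and stride as configured", {
  x <- array(rnorm(4 * 12 * 2), dim = c(4, 12, 2))
  p <- list(c1 = leadwise:::can_init(4, 2, 1),
            c2 = leadwise:::can_init(2, 2, 3),
            c3 = leadwise:::can_init(2, 4, 1))
  for (nm in c("c1", "c2", "c3")) p[[nm]]$w[] <- 0
  st <- list(c1 = list(run_mean = rep(0, 2), run_var = rep(1, 2)),
             c2 = list(run_mean = rep(0, 2), run_var = rep(1, 2)),
             c3 = list(run_mean = rep(0, 4), run_var = rep(1, 4)))
  out <- leadwise:::res_block_forward(x, p, st, training = TRUE, stride = 1,
                                      order = "relu_bn")
  expect_equal(out$out, x)  # identity shortcut survives a dead main path

  # stride-2 block halves the temporal length (ceiling division)
  cfg <- encoder_config(base_channels = 4, branch_channels = 2,
                        stem_kernel = 5, block_strides = c(1, 1, 2))
  expect_equal(encoder_out_shape(64, cfg)$t_out, 16)   # 64 -> 32 -> 32 -> 32 -> 16
  expect_equal(encoder_out_shape(65, cfg)$t_out, 17)   # ceil chain
  expect_equal(encoder_out_shape(1900, cfg)$t_out, 475)
})

test_that("expansion branches concatenate to 4c channels and stay sliceable", {
  cfg <- encoder_config(base_channels = 4, branch_channels = 3, stem_kernel = 5)
  set.seed(1)
  p <- leadwise:::encoder_init(cfg)
  st <- leadwise:::encoder_bn_state(cfg)
  x <- array(rnorm(1 * 32 * 2), dim = c(1, 32, 2))
  out <- leadwise:::encoder_forward(x, p, st, training = TRUE, cfg)
  expect_equal(dim(out$out)[1], 4 * 3)

  # zero input stays zero through the whole (bias-free init) encoder
  z <- leadwise:::encoder_forward(array(0, dim = c(1, 32, 2)), p, st,
                                  training = TRUE, cfg)
  expect_true(all(abs(z$out) < 1e-12))
})

test_that("lead encoding instantiates one group per lead and is permutation-equivariant", {
  cfg <- encoder_config(base_channels = 4, branch_channels = 2,
                        stem_kernel = 5, share_across_leads = TRUE)
  set.seed(2)
  p <- leadwise:::encoder_init(cfg)
  st <- leadwise:::encoder_bn_state(cfg)
  m <- 2; n <- 3; l <- 32
  set.seed(3)
  inputs <- array(rnorm(m * n * l), dim = c(m, n, l))
  ef <- leadwise:::encode_leads_forward(inputs, p, st, training = FALSE, cfg)
  expect_length(ef$feats, n)
  dims <- unique(lapply(ef$feats, dim))
  expect_length(dims, 1)

  perm <- c(2, 3, 1)
  ef_p <- leadwise:::encode_leads_forward(inputs[, perm, , drop = FALSE], p, st,
                                          training = FALSE, cfg)
  for (i in seq_len(n)) {
    expect_equal(ef_p$feats[[i]], ef$feats[[perm[i]]], tolerance = 1e-12)
  }

  expect_error(leadwise:::encode_leads_forward(
    array(0, dim = c(2, 1, 32)), p, st, FALSE, cfg), "at least 2")
})

test_that("a 12-lead model instantiates 12 encoder groups", {
  model <- build_model(tiny_config(n_leads = 12))
  counts <- model_component_counts(model)
  expect_equal(counts$count[counts$component == "encoder_groups"], 12)
})
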