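test_that("dynamic batch weights follow 1 - count/M + xi", {
  bw <- batch_class_weights(rep(1, 32), k_classes = 5)
  expect_equal(bw$c[1], 0.01)          # single-class batch -> exactly xi
  expect_equal(bw$c[2], 1.01)          # absent class -> 1 + xi

  bw2 <- batch_class_weights(c(1, 1, 2, 3), k_classes = 4)
  expect_equal(bw2$c, c(0.51, 0.76, 0.76, 1.01))

  labs <- batch_class_weights(c("MI", "MI", "N"), k_classes = 5,
                              class_names = task1_classes())
  expect_equal(labs$c[3], 1 - 2 / 3 + 0.01)

  expect_error(batch_class_weights(integer(0), 5), "at least one")
  expect_error(batch_class_weights(c(1, 9), 5), "outside")
})

test_that("weights are bounded, favour minorities and decrease in class count", {
  set.seed(41)
  for (rep in 1:20) {
    m <- sample(2:40, 1)
    k <- sample(2:15, 1)
    labels <- sample(k, m, replace = TRUE)
    bw <- batch_class_weights(labels, k)
    expect_true(all(bw$c >= bw$xi - 1e-12))
    expect_true(all(bw$c <= 1 + bw$xi + 1e-12))
    counts <- tabulate(labels, k)
    present <- which(counts > 0)
    if (length(present) > 1) {
      minority <- present[which.min(counts[present])]
      majority <- present[which.max(counts[present])]
      if (counts[minority] < counts[majority]) {
        expect_gt(bw$c[minority], bw$c[majority])
      }
    }
  }
  # strict monotonicity in a class's own count
  w_k <- function(cnt, m) batch_class_weights(
    c(rep(1, cnt), rep(2, m - cnt)), 2)$c[1]
  expect_true(all(diff(vapply(1:9, w_k, numeric(1), m = 10)) < 0))
})

test_that("weighted cross-entropy matches hand values and the unweighted oracle", {
  # perfect predictions cost nothing
  p <- diag(3)[c(1, 2, 3), ]
  expect_equal(weighted_cross_entropy(p, 1:3, rep(1, 3)), 0, tolerance = 1e-9)

  # forced-uniform weights equal an independently computed cross-entropy sum
  set.seed(42)
  logits <- matrix(rnorm(5 * 4), 5, 4)
  probs <- exp(logits) / rowSums(exp(logits))
  labels <- sample(4, 5, replace = TRUE)
  ref <- -sum(log(probs[cbind(1:5, labels)]))
  expect_equal(weighted_cross_entropy(probs, labels, rep(1, 4)), ref,
               tolerance = 1e-12)

  # M=2, K=2, both rows (0.5, 0.5), c = 0.51 -> 2 * 0.51 * ln 2
  p2 <- matrix(0.5, 2, 2)
  expect_equal(weighted_cross_entropy(p2, c(1, 2), c(0.51, 0.51)),
               2 * 0.51 * log(2), tolerance = 1e-12)

  expect_error(weighted_cross_entropy(matrix(c(0.9, 0.3), 1), 1, c(1, 1)),
               "sum to 1")
})

test_that("weight vanishing with xi recovers plain cross-entropy scaling", {
  set.seed(43)
  probs <- matrix(stats::runif(12, 0.1, 1), 4, 3)
  probs <- probs / rowSums(probs)
  labels <- c(1, 2, 3, 1)
  # uniform batch composition: every class appears equally often
  bal_labels <- c(1, 2, 3, 1, 2, 3)
  bw <- batch_class_weights(bal_labels, 3, xi = 1e-9)
  expect_equal(max(bw$c) - min(bw$c), 0, tolerance = 1e-12)
  w_loss <- weighted_cross_entropy(probs, labels, bw)
  u_loss <- weighted_cross_entropy(probs, labels, rep(1, 3))
  expect_equal(w_loss / u_loss, unname(bw$c[1]), tolerance = 1e-6)
})

test_that("the joint loss is the exact convex combination", {
  expect_equal(joint_loss(2, 1, 1), 2)
  expect_equal(joint_loss(2, 1, 0), 1)
  expect_equal(joint_loss(2, 1, 0.2), 1.2)
  set.seed(44)
  for (i in 1:10) {
    l1 <- runif(1, 0, 5); l2 <- runif(1, 0, 5); lam <- runif(1)
    expect_equal(joint_loss(l1, l2, lam), lam * l1 + (1 - lam) * l2)
    # monotone in each task loss
    expect_gte(joint_loss(l1 + 1, l2, lam), joint_loss(l1, l2, lam))
    expect_gte(joint_loss(l1, l2 + 1, lam), joint_loss(l1, l2, lam))
  }
  expect_error(joint_loss(1, 1, 1.2), "\\[0, 1\\]")
  expect_error(loss_config(xi = 0), "positive")
})
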