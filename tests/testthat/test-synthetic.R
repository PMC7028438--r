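no_noise <- list(white_sd = 0, wander_amp = 0)

test_that("generate_beat renders Gaussian wave sums correctly", {
  silent <- beat_morphology(
    wave_amplitudes = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  expect_equal(generate_beat(silent, fs = 500, rr = 0.8), rep(0, 400))

  r_only <- beat_morphology(
    wave_amplitudes = c(P = 0, Q = 0, R = 1, S = 0, T = 0))
  y <- generate_beat(r_only, fs = 500, rr = 0.8)
  expect_length(y, 400)                     # round(0.8 * 500)
  expect_equal(max(y), 1.0, tolerance = 1e-12)  # R centre lies on the grid
  expect_equal(which.max(y), 126L)          # t = 0.25 s, 0-based sample 125

  expect_error(generate_beat(r_only, fs = -1, rr = 0.8), "positive")
  expect_error(generate_beat(r_only, fs = 500, rr = 0), "positive")
})

test_that("generate_record matches the clinical record geometry and is deterministic", {
  rec <- generate_record("N", duration = 10, fs = 500, seed = 7)
  expect_equal(dim(rec$signal), c(12L, 5000L))
  expect_identical(rec$labels$task1, "N")

  rec2 <- generate_record("N", duration = 10, fs = 500, seed = 7)
  expect_identical(rec$signal, rec2$signal)

  rec3 <- generate_record("N", duration = 10, fs = 500, seed = 8)
  expect_false(identical(rec$signal, rec3$signal))

  expect_error(generate_record("XYZ", seed = 1), "unknown")
  expect_error(generate_record("N", duration = 1, fs = 500, seed = 1),
               "two mean RR")
})

test_that("anterior infarction shifts the ST window on V2 by the configured delta", {
  fixed_n <- class_effect("N", rr_sd = 0)
  fixed_ami <- class_effect("AMI", rr_sd = 0,
                            affected_leads = c("V1", "V2", "V3", "V4"),
                            amp_scale = c(Q = 2), st_delta = 0.2)
  rec_n <- generate_record("N", duration = 4, fs = 100, effect = fixed_n,
                           noise = no_noise, seed = 5)
  rec_a <- generate_record("AMI", duration = 4, fs = 100, effect = fixed_ami,
                           noise = no_noise, seed = 5)
  st_mean <- function(rec) {
    fs <- rec$fs
    vals <- c()
    for (k in 0:3) {
      idx <- seq(round((0.8 * k + 0.30) * fs), round((0.8 * k + 0.39) * fs)) + 1
      idx <- idx[idx <= ncol(rec$signal)]
      vals <- c(vals, rec$signal["V2", idx])
    }
    mean(vals)
  }
  expect_equal(st_mean(rec_a) - st_mean(rec_n), 0.2, tolerance = 0.02)
})

test_that("morphology classes separate under vanishing noise (nearest centroid)", {
  fixed_n <- class_effect("N", rr_sd = 0)
  fixed_ami <- class_effect("AMI", rr_sd = 0,
                            affected_leads = c("V1", "V2", "V3", "V4"),
                            st_delta = 0.2)
  st_feature <- function(rec) {
    fs <- rec$fs
    idx <- unlist(lapply(0:3, function(k) {
      seq(round((0.8 * k + 0.30) * fs), round((0.8 * k + 0.39) * fs)) + 1
    }))
    mean(rec$signal["V2", idx[idx <= ncol(rec$signal)]])
  }
  labels <- rep(c("N", "AMI"), each = 50)
  feats <- vapply(seq_along(labels), function(i) {
    eff <- if (labels[i] == "N") fixed_n else fixed_ami
    st_feature(generate_record(labels[i], duration = 4, fs = 100,
                               effect = eff, noise = no_noise, seed = 1000 + i))
  }, numeric(1))
  cen_n <- mean(feats[labels == "N"])
  cen_a <- mean(feats[labels == "AMI"])
  pred <- ifelse(abs(feats - cen_n) < abs(feats - cen_a), "N", "AMI")
  expect_equal(mean(pred == labels), 1.0)
})

test_that("generate_dataset respects priors, hierarchy and determinism", {
  one_hot <- stats::setNames(rep(0, 15), task2_classes())
  one_hot["N"] <- 1
  ds <- generate_dataset(10, class_priors = one_hot, duration = 3, fs = 50,
                         seed = 9)
  expect_length(ds$records, 10)
  expect_true(all(ds$manifest$task2 == "N"))
  expect_true(all(ds$manifest$task1 == "N"))

  expect_equal(unname(clinical_priors()["N"]), 0.6110)
  expect_equal(unname(clinical_priors()["SA"]), 0.1814)
  expect_equal(unname(clinical_priors()["AA"]), 0.0772)
  expect_equal(sum(clinical_priors()), 1, tolerance = 1e-12)

  ds2 <- generate_dataset(5, duration = 3, fs = 50, seed = 31)
  ds3 <- generate_dataset(5, duration = 3, fs = 50, seed = 31)
  expect_identical(lapply(ds2$records, `[[`, "signal"),
                   lapply(ds3$records, `[[`, "signal"))
  expect_identical(ds2$manifest, ds3$manifest)
  expect_identical(ds2$manifest$task1, map_task2_to_task1(ds2$manifest$task2))

  bad <- clinical_priors()
  bad["N"] <- -0.1
  expect_error(generate_dataset(5, class_priors = bad, seed = 1), "nonnegative")
})

test_that("uniform-prior class counts stay within the multinomial 3-SD band", {
  unif <- stats::setNames(rep(1 / 15, 15), task2_classes())
  ds <- generate_dataset(2000, class_priors = unif, duration = 3, fs = 50,
                         lead_names = c("I", "II"), seed = 77)
  counts <- table(factor(ds$manifest$task2, levels = task2_classes()))
  expected <- 2000 / 15
  sd3 <- 3 * sqrt(2000 * (1 / 15) * (14 / 15))
  expect_true(all(abs(counts - expected) <= sd3))
})

test_that("generator supports arbitrary lead subsets in requested order", {
  rec <- generate_record("N", duration = 3, fs = 50,
                         projection = lead_projection(c("V6", "II", "aVF")),
                         seed = 2)
  expect_identical(rec$lead_names, c("V6", "II", "aVF"))
  expect_equal(nrow(rec$signal), 3)
  expect_error(lead_projection("II"), "at least 2")
  expect_error(lead_projection(c("II", "Z9")), "unknown lead")
})
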