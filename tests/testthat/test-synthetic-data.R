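test_that("labels, masks and signatures are consistent", {
  spec <- synthetic_image_spec(height = 24, width = 24, n_images = 30,
                               label_names = c("a", "b"),
                               prevalence = c(0.5, 0.3), seed = 3)
  dat <- generate_images(spec)
  expect_length(dat$images, 30)
  expect_equal(dim(dat$labels), c(30L, 2L))
  for (i in seq_len(30)) {
    for (lab in c("a", "b")) {
      nonempty <- any(dat$truth_masks[[i]][[lab]])
      expect_identical(nonempty, unname(dat$labels[i, lab] == 1L))
    }
  }
  # signature pixels are brighter than background on positives
  pos <- which(dat$labels[, "a"] == 1L)[1]
  m <- dat$truth_masks[[pos]]$a
  expect_gt(mean(dat$images[[pos]][m]), mean(dat$images[[pos]][!m]))
})

test_that("zero prevalence yields all-negative labels and empty masks", {
  spec <- synthetic_image_spec(height = 16, width = 16, n_images = 10,
                               label_names = "x", prevalence = 0,
                               landmark_prob = 0, seed = 1)
  dat <- generate_images(spec)
  expect_true(all(dat$labels == 0L))
  expect_false(any(vapply(dat$truth_masks,
                          function(tm) any(tm$x), logical(1))))
})

test_that("image generation is deterministic under a fixed seed", {
  spec <- synthetic_image_spec(height = 16, width = 16, n_images = 5,
                               label_names = "x", prevalence = 0.5, seed = 9)
  d1 <- generate_images(spec)
  d2 <- generate_images(spec)
  expect_identical(d1, d2)
})

test_that("positive fraction matches the prevalence binomially", {
  n <- 1000
  spec <- synthetic_image_spec(height = 8, width = 8, n_images = n,
                               label_names = "x", prevalence = 0.3,
                               geometry = list(x = signature_geometry(
                                 "disc", c(4, 4), 2)),
                               landmark_prob = 0, seed = 4)
  dat <- generate_images(spec)
  frac <- mean(dat$labels[, "x"])
  sd3 <- 3 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(frac - 0.3), sd3)
})

test_that("landmarks are tiny, saturated, and removed by quantile clipping", {
  spec <- synthetic_image_spec(height = 64, width = 64, n_images = 40,
                               label_names = "x", prevalence = 0.5,
                               landmark_prob = 1, seed = 6)
  dat <- generate_images(spec)
  for (i in 1:5) {
    img <- dat$images[[i]]
    lm <- max(img)
    rest <- img[img < lm]
    expect_gte(lm, 10 * quantile(rest, 0.99, names = FALSE))
    # at most 0.02% of pixels (floor, but never zero)
    expect_lte(sum(img == lm), max(1, floor(2e-4 * length(img))))
    clipped <- clip_quantile(img, 0.9995)
    expect_lt(max(clipped), lm)
  }
})

test_that("out-of-bounds signature geometry is rejected", {
  expect_error(
    synthetic_image_spec(height = 16, width = 16, n_images = 2,
                         label_names = "x", prevalence = 0.5,
                         geometry = list(x = signature_geometry(
                           "disc", c(2, 2), 6))),
    "exceeds image bounds"
  )
})

test_that("prediction generator spans the skill/calibration contract", {
  set.seed(1)
  labels <- matrix(rbinom(2000, 1, 0.4), ncol = 1)
  # uninformative: AUC ~ 0.5
  p0 <- generate_predictions(
    synthetic_prediction_spec(1, skill = 0, calibration = "uninformative",
                              seed = 2), labels)
  expect_true(all(p0 >= 0 & p0 <= 1))
  expect_lt(abs(roc_auc(p0[1, 1, ], labels[, 1])$auc - 0.5), 0.05)
  expect_true(all(abs(p0 - 0.5) < 0.3)) # concentrated near one half
  # infinite separation: AUC exactly 1
  p1 <- generate_predictions(
    synthetic_prediction_spec(1, skill = Inf, seed = 3), labels)
  expect_equal(roc_auc(p1[1, 1, ], labels[, 1])$auc, 1)
  # overconfident: >= 90% of mass outside [0.2, 0.8]
  p2 <- generate_predictions(
    synthetic_prediction_spec(1, skill = 2, calibration = "overconfident",
                              seed = 4), labels)
  expect_gte(mean(p2 < 0.2 | p2 > 0.8), 0.9)
  # higher skill -> higher AUC
  lo <- generate_predictions(synthetic_prediction_spec(1, skill = 0.5,
                                                       seed = 5), labels)
  hi <- generate_predictions(synthetic_prediction_spec(1, skill = 3,
                                                       seed = 5), labels)
  expect_gt(roc_auc(hi[1, 1, ], labels[, 1])$auc,
            roc_auc(lo[1, 1, ], labels[, 1])$auc)
})

test_that("embedding generator shifts informative dimensions as configured", {
  set.seed(2)
  labels <- matrix(rbinom(600, 1, 0.5), ncol = 1,
                   dimnames = list(NULL, "y"))
  # zero effect: class means equal within noise
  e0 <- generate_embeddings(
    synthetic_embedding_spec(dim = 8, effect_size = 0, seed = 3), labels)
  gap <- abs(mean(e0[labels == 1, 1]) - mean(e0[labels == 0, 1]))
  expect_lt(gap, 4 / sqrt(300))
  # strong effect: near-perfect separation by a held-out threshold rule
  e5 <- generate_embeddings(
    synthetic_embedding_spec(dim = 8, effect_size = 5, noise_sd = 1,
                             seed = 3), labels)
  info <- attr(e5, "informative")$y[1]
  train <- seq_len(300)
  thr <- (mean(e5[train, info][labels[train] == 1]) +
          mean(e5[train, info][labels[train] == 0])) / 2
  acc <- mean((e5[-train, info] > thr) == (labels[-train] == 1))
  expect_gte(acc, 0.99)
  # determinism
  expect_identical(e5, generate_embeddings(
    synthetic_embedding_spec(dim = 8, effect_size = 5, noise_sd = 1,
                             seed = 3), labels))
})
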