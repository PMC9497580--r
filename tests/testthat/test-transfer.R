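test_that("label mapping aggregates source scores by maximum", {
  mp <- cxr_label_mapping()
  src <- matrix(0.1, 2, 14)
  colnames(src) <- c("no_finding", "enlarged_cardiomediastinum",
                     "cardiomegaly", "lung_opacity", "lung_lesion", "edema",
                     "consolidation", "pneumonia", "atelectasis",
                     "pneumothorax", "pleural_effusion", "pleural_other",
                     "fracture", "support_devices")
  src[1, "enlarged_cardiomediastinum"] <- 0.35
  src[1, "cardiomegaly"] <- 0.6
  src[1, "fracture"] <- 0.42
  out <- map_predictions(src, mp)
  expect_equal(colnames(out), mp$target_labels)
  expect_equal(unname(out[1, "cardiac"]), 0.6)   # max of its two sources
  expect_equal(unname(out[1, "bone"]), 0.42)     # singleton passes through
  expect_equal(unname(out[2, "cardiac"]), 0.1)
})

test_that("max aggregation picks the largest of several sources", {
  mp <- label_mapping(list(lung = 1:3))
  expect_equal(unname(map_predictions(matrix(c(0.2, 0.7, 0.4), 1, 3), mp)[1, 1]), 0.7)
})

test_that("mapping is monotone in every source probability", {
  mp <- label_mapping(list(t1 = 1:2, t2 = 3))
  set.seed(3)
  for (rep in 1:20) {
    P <- matrix(runif(9), 3, 3)
    base <- map_predictions(P, mp)
    i <- sample(3, 1); j <- sample(3, 1)
    P2 <- P
    P2[i, j] <- min(1, P[i, j] + runif(1, 0, 1 - P[i, j]))
    expect_true(all(map_predictions(P2, mp) >= base))
  }
})

test_that("mapping validates its configuration", {
  expect_error(label_mapping(list(t1 = integer(0))), "at least one source")
  expect_error(label_mapping(list(t1 = "x"), source_labels = c("a", "b")),
               "unknown source")
  mp <- label_mapping(list(t1 = 5))
  expect_error(map_predictions(matrix(0.5, 2, 3), mp), "out of range")
})

test_that("per-sample mapping matches the single-matrix operation", {
  mp <- label_mapping(list(t1 = 1:2, t2 = 3))
  set.seed(4)
  arr <- array(runif(2 * 3 * 5), c(2, 3, 5))
  out <- map_predictions(arr, mp)
  expect_equal(dim(out), c(2L, 2L, 5L))
  for (i in 1:5) {
    expect_equal(out[, , i], map_predictions(arr[, , i], mp),
                 ignore_attr = TRUE)
  }
})

test_that("extracted embeddings equal the brute-force spatial mean", {
  net <- tiny_net(n_labels = 2, seed = 6)
  imgs <- lapply(1:4, function(s) random_image(16, seed = s))
  emb <- extract_embeddings(net, imgs)
  fmaps <- cnn_feature_maps(net, imgs)
  brute <- t(apply(fmaps, c(3, 4), mean))
  expect_lt(max(abs(emb - brute)), 1e-6)
  expect_identical(emb, extract_embeddings(net, imgs))
  expect_error(extract_embeddings(list(), imgs), "GAP")
})

test_that("stratified split respects fractions and keeps rare positives", {
  set.seed(5)
  labels <- cbind(common = rbinom(200, 1, 0.5), rare = rbinom(200, 1, 0.1))
  sp <- stratified_split(labels, c(0.7, 0.1, 0.2), seed = 2)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:200)
  expect_equal(length(sp$train) / 200, 0.7, tolerance = 0.02)
  # rare positives present in train and test
  expect_gt(sum(labels[sp$train, "rare"]), 0)
  expect_gt(sum(labels[sp$test, "rare"]), 0)
})

test_that("grid search enumerates every cell and picks the single cell", {
  set.seed(6)
  labels <- matrix(rbinom(120, 1, 0.5), ncol = 1,
                   dimnames = list(NULL, "y"))
  emb <- generate_embeddings(
    synthetic_embedding_spec(dim = 6, effect_size = 2, seed = 7), labels)
  cfg1 <- tree_grid_config("DT", max_depth = 3, min_samples_leaf = 2,
                           min_samples_split = 2, criterion = "gini",
                           k_folds = 3, seed = 1)
  fit1 <- fit_tree_classifier(emb, labels, cfg1)
  expect_equal(nrow(fit1$cv_table), 1L)
  expect_equal(fit1$best$max_depth, 3)
  cfg2 <- tree_grid_config("RF", max_depth = c(2, 5),
                           min_samples_leaf = c(1, 4),
                           min_samples_split = c(2, 10),
                           criterion = c("gini", "entropy"),
                           n_estimators = c(20, 50), k_folds = 3, seed = 1)
  fit2 <- fit_tree_classifier(emb, labels, cfg2)
  expect_equal(nrow(fit2$cv_table), 2 * 2 * 2 * 2 * 2)
})

test_that("grid search selection ignores grid enumeration order", {
  set.seed(8)
  labels <- matrix(rbinom(100, 1, 0.5), ncol = 1,
                   dimnames = list(NULL, "y"))
  emb <- generate_embeddings(
    synthetic_embedding_spec(dim = 6, effect_size = 1.5, seed = 9), labels)
  a <- fit_tree_classifier(emb, labels, tree_grid_config(
    "DT", max_depth = c(1, 3, 10), min_samples_leaf = c(4, 1),
    min_samples_split = 2, criterion = "gini", k_folds = 3, seed = 2))
  b <- fit_tree_classifier(emb, labels, tree_grid_config(
    "DT", max_depth = c(10, 1, 3), min_samples_leaf = c(1, 4),
    min_samples_split = 2, criterion = "gini", k_folds = 3, seed = 2))
  expect_identical(a$best, b$best)
  expect_identical(a$cv_table$mean_cv_auc, b$cv_table$mean_cv_auc)
})

test_that("trees on strongly separable embeddings classify held-out data", {
  set.seed(10)
  labels <- matrix(rbinom(300, 1, 0.5), ncol = 1,
                   dimnames = list(NULL, "y"))
  emb <- generate_embeddings(
    synthetic_embedding_spec(dim = 8, effect_size = 5, noise_sd = 1,
                             seed = 11), labels)
  sp <- stratified_split(labels, c(0.7, 0.3), seed = 3)
  cfg <- tree_grid_config("RF", max_depth = c(3, 10), min_samples_leaf = 1,
                          min_samples_split = 2, criterion = "gini",
                          n_estimators = 100, k_folds = 3, seed = 4)
  fit <- fit_tree_classifier(emb[sp$train, ], labels[sp$train, , drop = FALSE],
                             cfg)
  p <- predict(fit, emb[sp$test, ])
  expect_gte(roc_auc(p[, 1], labels[sp$test, 1])$auc, 0.95)
})

test_that("single-class labels are skipped with a warning", {
  set.seed(12)
  labels <- cbind(y = rbinom(80, 1, 0.5), z = rep(0L, 80))
  emb <- matrix(rnorm(80 * 4), 80, 4)
  cfg <- tree_grid_config("DT", max_depth = 3, min_samples_leaf = 1,
                          min_samples_split = 2, criterion = "gini",
                          k_folds = 2, seed = 1)
  expect_warning(fit <- fit_tree_classifier(emb, labels, cfg), "single-class")
  p <- predict(fit, emb)
  expect_true(all(is.na(p[, "z"])))
  expect_false(anyNA(p[, "y"]))
})

test_that("stacking learns from informative bases and not from noise", {
  set.seed(13)
  labels <- matrix(rbinom(400, 1, 0.5), ncol = 1,
                   dimnames = list(NULL, "y"))
  sp <- stratified_split(labels, c(0.7, 0.3), seed = 5)
  # perfectly predictive bases
  perfect <- generate_predictions(
    synthetic_prediction_spec(3, skill = Inf, seed = 6), labels)
  expect_equal(dim(stacking_features(perfect)), c(400L, 3L))
  st <- fit_stacking(perfect[, , sp$train, drop = FALSE],
                     labels[sp$train, , drop = FALSE], seed = 1)
  p <- predict(st, perfect[, , sp$test, drop = FALSE])
  expect_equal(roc_auc(p[, 1], labels[sp$test, 1])$auc, 1)
  # uninformative bases: chance level
  noise <- generate_predictions(
    synthetic_prediction_spec(3, skill = 0, calibration = "uninformative",
                              seed = 7), labels)
  st0 <- fit_stacking(noise[, , sp$train, drop = FALSE],
                      labels[sp$train, , drop = FALSE], seed = 1)
  p0 <- predict(st0, noise[, , sp$test, drop = FALSE])
  expect_lt(abs(roc_auc(p0[, 1], labels[sp$test, 1])$auc - 0.5), 0.15)
})

test_that("fine-tuning follows the learning-rate schedule and checkpoints", {
  fix <- blob_fixture()
  dat <- fix$dat
  sp <- stratified_split(dat$labels, c(0.6, 0.2, 0.2), seed = 6)
  ft <- fine_tune(
    fix$model,
    train = list(images = fix$x[sp$train],
                 labels = dat$labels[sp$train, , drop = FALSE]),
    val = list(images = fix$x[sp$val],
               labels = dat$labels[sp$val, , drop = FALSE]),
    cfg = fine_tune_config(), seed = 3
  )
  h <- ft$history
  expect_equal(h$lr, 1e-4 * 10^-(h$epoch - 1))
  expect_lte(nrow(h), 5)
  expect_gte(max(h$val_auc), 0.9) # blob-task transfer reaches high val AUC
  expect_equal(ft$model$n_labels, 1L)
  expect_error(
    fine_tune(fix$model, train = list(images = fix$x[1:4],
                                      labels = dat$labels[1:4, , drop = FALSE]),
              val = list(images = list())),
    "validation"
  )
})

test_that("early stopping halts after patience epochs without improvement", {
  fix <- blob_fixture()
  dat <- fix$dat
  sp <- stratified_split(dat$labels, c(0.6, 0.2, 0.2), seed = 6)
  # val AUC saturates at 1 immediately, so improvement stalls after epoch 1
  ft <- fine_tune(
    fix$model,
    train = list(images = fix$x[sp$train],
                 labels = dat$labels[sp$train, , drop = FALSE]),
    val = list(images = fix$x[sp$val],
               labels = dat$labels[sp$val, , drop = FALSE]),
    cfg = fine_tune_config(patience = 2), seed = 3
  )
  if (max(ft$history$val_auc) >= 1) {
    expect_lte(nrow(ft$history), 1 + 2)
  }
  expect_equal(ft$best_epoch, which.max(ft$history$val_auc))
})
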