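# The four transfer strategies: direct mapped inference (max-probability
# aggregation over a source-to-target label correspondence), stacked
# generalization with a random-forest metaclassifier, tree classifiers on
# pooled convolutional embeddings with exhaustive grid search under
# stratified K-fold cross validation, and fine-tuning of a replaced
# classification head.

# ---- label mapping ---------------------------------------------------------

#' Cross-dataset label mapping
#'
#' Associates each target label with a nonempty set of source labels; a
#' target score is the maximum of its sources' scores.
#'
#' @param source_sets Named list: one entry per target label (in order),
#'   each a character or integer vector of source labels.
#' @param source_labels Optional character vector naming the source label
#'   space (required to resolve character source sets at mapping time is not
#'   needed; used for validation when provided).
#' @return A `label_mapping`.
#' @export
label_mapping <- function(source_sets, source_labels = NULL) {
  stopifnot(is.list(source_sets), length(source_sets) >= 1L,
            !is.null(names(source_sets)), all(nzchar(names(source_sets))))
  if (any(lengths(source_sets) == 0L)) {
    stop("every target label needs at least one source label", call. = FALSE)
  }
  if (!is.null(source_labels)) {
    for (s in source_sets) {
      if (is.character(s) && !all(s %in% source_labels)) {
        stop("unknown source label: ",
             paste(setdiff(s, source_labels), collapse = ", "), call. = FALSE)
      }
      if (is.numeric(s) && any(s < 1 | s > length(source_labels))) {
        stop("source index out of range", call. = FALSE)
      }
    }
  }
  structure(list(target_labels = names(source_sets),
                 source_sets = source_sets,
                 source_labels = source_labels),
            class = "label_mapping")
}

#' Built-in example mapping between a 14-finding source label space and a
#' 7-finding target label space
#'
#' The correspondence used when a model trained on a large public
#' chest-radiograph label set is applied to a coarser local label set:
#' e.g. target "cardiac" is the maximum over "enlarged_cardiomediastinum"
#' and "cardiomegaly".
#'
#' @return A [label_mapping()].
#' @export
cxr_label_mapping <- function() {
  label_mapping(list(
    pleura = c("pleural_effusion", "pleural_other"),
    device = "support_devices",
    pnx = "pneumothorax",
    cardiac = c("enlarged_cardiomediastinum", "cardiomegaly"),
    lung = c("lung_opacity", "lung_lesion", "consolidation",
             "pneumonia", "atelectasis", "edema"),
    bone = "fracture",
    normal = "no_finding"
  ))
}

.resolve_sources <- function(mapping, source_names, L_s) {
  lapply(mapping$source_sets, function(s) {
    if (is.character(s)) {
      if (is.null(source_names)) stop("prediction matrix has no source label names",
                                      call. = FALSE)
      idx <- match(s, source_names)
      if (anyNA(idx)) stop("unknown source label: ",
                           paste(s[is.na(idx)], collapse = ", "), call. = FALSE)
      idx
    } else {
      idx <- as.integer(s)
      if (any(idx < 1L | idx > L_s)) stop("source index out of range",
                                          call. = FALSE)
      idx
    }
  })
}

#' Map source-label predictions to target labels by max aggregation
#'
#' Each target label's score is the maximum of the scores of its source
#' labels, per classifier; singleton source sets pass through unchanged.
#' Raising any source probability can never lower a target score.
#'
#' @param source_preds `K x L_s` matrix or `(K, L_s, n)` array of
#'   probabilities, with source labels as column names (required when the
#'   mapping refers to sources by name).
#' @param mapping A [label_mapping()].
#' @return A `K x L_t` matrix (or `(K, L_t, n)` array) of target scores.
#' @export
map_predictions <- function(source_preds, mapping) {
  stopifnot(inherits(mapping, "label_mapping"))
  if (length(dim(source_preds)) == 3L) {
    srcs <- .resolve_sources(mapping, dimnames(source_preds)[[2L]],
                             dim(source_preds)[2L])
    d <- dim(source_preds)
    out <- array(NA_real_, c(d[1L], length(srcs), d[3L]),
                 dimnames = list(dimnames(source_preds)[[1L]],
                                 mapping$target_labels,
                                 dimnames(source_preds)[[3L]]))
    for (j in seq_along(srcs)) {
      sub <- source_preds[, srcs[[j]], , drop = FALSE]
      out[, j, ] <- apply(sub, c(1L, 3L), max)
    }
    return(out)
  }
  P <- as.matrix(source_preds)
  srcs <- .resolve_sources(mapping, colnames(P), ncol(P))
  out <- vapply(srcs, function(idx) {
    apply(P[, idx, drop = FALSE], 1L, max)
  }, numeric(nrow(P)))
  out <- matrix(out, nrow = nrow(P),
                dimnames = list(rownames(P), mapping$target_labels))
  out
}

# ---- embeddings ------------------------------------------------------------

#' Extract GAP image embeddings from a model
#'
#' One row per image: the channel-wise spatial mean of the model's final
#' convolutional feature maps (its global-average-pooled feature vector).
#'
#' @param model A model exposing GAP features ([build_fixture_cnn()] object).
#' @param images Images (list, batch array, or single image).
#' @return `n x d` embedding matrix with attribute `"extractor_id"`.
#' @export
extract_embeddings <- function(model, images) {
  if (!inherits(model, "fixture_cnn")) {
    stop("model does not expose convolutional features/GAP vector",
         call. = FALSE)
  }
  emb <- cnn_gap(model, images)
  colnames(emb) <- paste0("e", seq_len(ncol(emb)))
  attr(emb, "extractor_id") <- sprintf("fixture_cnn_seed%d", model$seed)
  emb
}

# ---- splits ----------------------------------------------------------------

#' Stratified train/validation/test split
#'
#' Stratifies on the positivity of the rarest label so that each part keeps
#' examples of the least frequent finding.
#'
#' @param labels Binary `n x L` matrix.
#' @param fractions Numeric vector summing to 1; length 2 (`train`, `test`)
#'   or 3 (`train`, `val`, `test`).
#' @param seed Integer seed.
#' @return Named list of integer index vectors (`train`, `val` if requested,
#'   `test`).
#' @export
stratified_split <- function(labels, fractions = c(0.7, 0.3), seed = 1L) {
  labels <- as.matrix(labels)
  stopifnot(abs(sum(fractions) - 1) < 1e-8,
            length(fractions) %in% c(2L, 3L))
  n <- nrow(labels)
  rare <- which.min(colMeans(labels))
  strata <- labels[, rare]
  set.seed(as.integer(seed))
  parts <- lapply(seq_along(fractions), function(i) integer(0))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    m <- length(idx)
    cuts <- round(cumsum(fractions) * m)
    start <- 1L
    for (i in seq_along(fractions)) {
      if (cuts[i] >= start) parts[[i]] <- c(parts[[i]], idx[start:cuts[i]])
      start <- cuts[i] + 1L
    }
  }
  parts <- lapply(parts, sort)
  names(parts) <- if (length(fractions) == 2L) c("train", "test")
                  else c("train", "val", "test")
  parts
}

# Stratified K folds on the rarest label; returns fold id per row.
.stratified_folds <- function(labels, k, seed) {
  labels <- as.matrix(labels)
  rare <- which.min(colMeans(labels))
  strata <- labels[, rare]
  set.seed(as.integer(seed))
  fold <- integer(nrow(labels))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# ---- tree classifiers on embeddings ----------------------------------------

#' Hyperparameter grid for tree-based classifiers
#'
#' Default grids match the reference configuration: max depth
#' {1,2,3,4,5,10,20}, min samples leaf {1,2,4}, min samples split {2,5,10},
#' criterion {gini, entropy}, and for the forest variants 10-300 trees.
#' Every grid cell is enumerated; axes a backend cannot express (the
#' split criterion and min-samples-split for the ranger-based RF/XRT) are
#' recorded in the CV table but not passed through.
#'
#' @param kind `"DT"` (decision tree), `"RF"` (random forest) or `"XRT"`
#'   (extremely randomized trees).
#' @param max_depth,min_samples_leaf,min_samples_split,criterion,n_estimators
#'   Grid axes; `n_estimators` is ignored for `"DT"`.
#' @param k_folds Stratified CV folds (>= 2).
#' @param seed Integer seed for folds and forest randomness.
#' @return A `tree_grid_config`.
#' @export
tree_grid_config <- function(kind = c("RF", "DT", "XRT"),
                             max_depth = c(1, 2, 3, 4, 5, 10, 20),
                             min_samples_leaf = c(1, 2, 4),
                             min_samples_split = c(2, 5, 10),
                             criterion = c("gini", "entropy"),
                             n_estimators = c(10, 20, 30, 50, 100, 200, 300),
                             k_folds = 5L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(k_folds >= 2L, length(max_depth) >= 1L,
            all(criterion %in% c("gini", "entropy")))
  if (kind == "DT") n_estimators <- NA_real_
  structure(list(kind = kind, max_depth = max_depth,
                 min_samples_leaf = min_samples_leaf,
                 min_samples_split = min_samples_split,
                 criterion = criterion, n_estimators = n_estimators,
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "tree_grid_config")
}

# Fit one tree-family model for one binary label; returns a predictor
# closure giving positive-class probabilities.
.fit_tree_cell <- function(kind, x, y, cell, seed) {
  df <- as.data.frame(x)
  yf <- factor(y, levels = c(0L, 1L))
  if (kind == "DT") {
    fit <- rpart::rpart(
      yf ~ ., data = cbind(df, yf = yf), method = "class",
      parms = list(split = if (cell$criterion == "entropy") "information"
                           else "gini"),
      control = rpart::rpart.control(
        maxdepth = min(cell$max_depth, 30L),
        minbucket = cell$min_samples_leaf,
        minsplit = cell$min_samples_split,
        cp = 0, xval = 0
      )
    )
    function(newx) {
      stats::predict(fit, as.data.frame(newx))[, "1"]
    }
  } else {
    extra <- kind == "XRT"
    fit <- ranger::ranger(
      y = yf, x = df, probability = TRUE,
      num.trees = cell$n_estimators,
      max.depth = cell$max_depth,
      min.node.size = cell$min_samples_leaf,
      splitrule = if (extra) "extratrees" else "gini",
      replace = !extra,
      sample.fraction = if (extra) 1 else 1,
      seed = seed, num.threads = 1L
    )
    function(newx) {
      stats::predict(fit, as.data.frame(newx), num.threads = 1L)$predictions[, "1"]
    }
  }
}

#' Grid-search a tree classifier on embeddings
#'
#' Exhaustively evaluates the hyperparameter grid by stratified K-fold cross
#' validation, scoring each cell by its mean AUC across folds and labels,
#' then refits one model per label on the full training data with the best
#' cell. Ties are broken by the fixed lexicographic order of the sorted grid
#' (so the result does not depend on how the grid was enumerated). Labels
#' with a single class in the training data are skipped with a warning.
#'
#' @param emb `n x d` embedding matrix (training split).
#' @param labels Binary `n x L` matrix aligned to `emb`.
#' @param cfg A [tree_grid_config()].
#' @return A `tree_classifier`: list with `predictors` (per label), `best`
#'   (chosen cell), `cv_table` (one row per cell with mean CV AUC),
#'   `kind`, `label_names`.
#' @export
fit_tree_classifier <- function(emb, labels, cfg) {
  stopifnot(inherits(cfg, "tree_grid_config"))
  emb <- as.matrix(emb)
  labels <- as.matrix(labels)
  stopifnot(nrow(emb) == nrow(labels))
  nms <- colnames(labels)
  if (is.null(nms)) nms <- paste0("label", seq_len(ncol(labels)))
  usable <- vapply(seq_len(ncol(labels)),
                   function(j) length(unique(labels[, j])) == 2L, logical(1))
  if (!any(usable)) stop("no label has both classes in training data",
                         call. = FALSE)
  if (!all(usable)) {
    warning("skipping single-class label(s): ",
            paste(nms[!usable], collapse = ", "))
  }
  grid <- expand.grid(
    max_depth = sort(cfg$max_depth),
    min_samples_leaf = sort(cfg$min_samples_leaf),
    min_samples_split = sort(cfg$min_samples_split),
    criterion = sort(cfg$criterion),
    n_estimators = if (cfg$kind == "DT") NA_real_ else sort(cfg$n_estimators),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  fold <- .stratified_folds(labels[, usable, drop = FALSE], cfg$k_folds,
                            cfg$seed)
  lab_idx <- which(usable)
  cv_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cell <- as.list(grid[g, ])
    aucs <- c()
    for (f in seq_len(cfg$k_folds)) {
      tr <- fold != f
      te <- !tr
      for (j in lab_idx) {
        ytr <- labels[tr, j]
        yte <- labels[te, j]
        if (length(unique(ytr)) < 2L || length(unique(yte)) < 2L) next
        pred <- .fit_tree_cell(cfg$kind, emb[tr, , drop = FALSE], ytr, cell,
                               seed = cfg$seed + g)
        a <- suppressWarnings(roc_auc(pred(emb[te, , drop = FALSE]), yte)$auc)
        if (!is.na(a)) aucs <- c(aucs, a)
      }
    }
    cv_auc[g] <- if (length(aucs)) mean(aucs) else NA_real_
  }
  cv_table <- cbind(grid, mean_cv_auc = cv_auc)
  best_i <- which.max(cv_auc) # first max = lexicographic tie-break
  best <- as.list(grid[best_i, ])
  predictors <- stats::setNames(vector("list", ncol(labels)), nms)
  for (j in lab_idx) {
    predictors[[j]] <- .fit_tree_cell(cfg$kind, emb, labels[, j], best,
                                      seed = cfg$seed)
  }
  structure(list(predictors = predictors, best = best, cv_table = cv_table,
                 kind = cfg$kind, label_names = nms),
            class = "tree_classifier")
}

#' Predict label probabilities with a fitted tree classifier
#'
#' @param object A `tree_classifier`.
#' @param newdata `n x d` embedding (or feature) matrix.
#' @param ... Unused.
#' @return `n x L` matrix of positive-class probabilities (`NA` columns for
#'   labels skipped during fitting).
#' @export
predict.tree_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- matrix(NA_real_, nrow(newdata), length(object$predictors),
                dimnames = list(NULL, object$label_names))
  for (j in seq_along(object$predictors)) {
    if (!is.null(object$predictors[[j]])) {
      out[, j] <- object$predictors[[j]](newdata)
    }
  }
  out
}

# ---- stacking --------------------------------------------------------------

#' Stacked generalization over mapped base predictions
#'
#' Flattens each sample's `K x L_t` mapped prediction matrix into a feature
#' vector of length `K * L_t` and trains one random-forest metaclassifier
#' per target label. By default the forest uses the reference selected
#' hyperparameters (100 trees, max depth 10, min leaf 4, gini); pass a
#' [tree_grid_config()] to grid-search instead.
#'
#' @param base_preds `(K, L_t, n)` array of mapped base-classifier
#'   predictions for the training samples.
#' @param labels Binary `n x L_t` matrix.
#' @param cfg Optional [tree_grid_config()]; `NULL` uses the fixed default.
#' @param per_label_features If `TRUE`, each label's metaclassifier sees only
#'   its own column of the K base predictions instead of all `K * L_t`.
#' @param seed Integer seed.
#' @return A `stacking_model` (a `tree_classifier` plus feature metadata).
#' @export
fit_stacking <- function(base_preds, labels, cfg = NULL,
                         per_label_features = FALSE, seed = 1L) {
  stopifnot(length(dim(base_preds)) == 3L)
  labels <- as.matrix(labels)
  K <- dim(base_preds)[1L]
  Lt <- dim(base_preds)[2L]
  stopifnot(dim(base_preds)[3L] == nrow(labels), Lt == ncol(labels))
  feats <- stacking_features(base_preds)
  if (is.null(cfg)) {
    cfg <- tree_grid_config("RF", max_depth = 10, min_samples_leaf = 4,
                            min_samples_split = 10, criterion = "gini",
                            n_estimators = 100, k_folds = 2L, seed = seed)
  }
  if (per_label_features) {
    nms <- colnames(labels)
    if (is.null(nms)) nms <- paste0("label", seq_len(Lt))
    predictors <- stats::setNames(vector("list", Lt), nms)
    best <- as.list(expand.grid(
      max_depth = cfg$max_depth[1], min_samples_leaf = cfg$min_samples_leaf[1],
      min_samples_split = cfg$min_samples_split[1],
      criterion = cfg$criterion[1], n_estimators = cfg$n_estimators[1],
      stringsAsFactors = FALSE
    ))
    for (j in seq_len(Lt)) {
      fj <- t(base_preds[, j, , drop = TRUE])
      if (K == 1L) fj <- matrix(base_preds[, j, ], ncol = 1L)
      if (length(unique(labels[, j])) < 2L) {
        warning("skipping single-class label: ", nms[j])
        next
      }
      predictors[[j]] <- .fit_tree_cell(cfg$kind, fj, labels[, j], best,
                                        seed = cfg$seed + j)
    }
    fit <- structure(list(predictors = predictors, best = best,
                          cv_table = NULL, kind = cfg$kind,
                          label_names = nms),
                     class = "tree_classifier")
  } else {
    fit <- fit_tree_classifier(feats, labels, cfg)
  }
  structure(list(fit = fit, K = K, target_labels = colnames(labels),
                 per_label_features = per_label_features),
            class = "stacking_model")
}

#' Flatten per-sample prediction matrices into stacking features
#'
#' @param base_preds `(K, L, n)` array.
#' @return `n x (K*L)` matrix, columns named `clf.label`.
#' @export
stacking_features <- function(base_preds) {
  d <- dim(base_preds)
  out <- t(matrix(base_preds, d[1L] * d[2L], d[3L]))
  cn <- outer(
    if (is.null(dimnames(base_preds)[[1L]])) paste0("clf", seq_len(d[1L]))
    else dimnames(base_preds)[[1L]],
    if (is.null(dimnames(base_preds)[[2L]])) paste0("label", seq_len(d[2L]))
    else dimnames(base_preds)[[2L]],
    paste, sep = "."
  )
  colnames(out) <- as.vector(cn)
  out
}

#' @export
predict.stacking_model <- function(object, base_preds, ...) {
  if (object$per_label_features) {
    d <- dim(base_preds)
    out <- matrix(NA_real_, d[3L], d[2L],
                  dimnames = list(NULL, object$fit$label_names))
    for (j in seq_len(d[2L])) {
      if (is.null(object$fit$predictors[[j]])) next
      fj <- t(base_preds[, j, , drop = TRUE])
      if (d[1L] == 1L) fj <- matrix(base_preds[, j, ], ncol = 1L)
      out[, j] <- object$fit$predictors[[j]](fj)
    }
    return(out)
  }
  stats::predict(object$fit, stacking_features(base_preds))
}

# ---- fine-tuning -----------------------------------------------------------

#' Fine-tuning configuration
#'
#' Defaults follow the reference protocol: five epochs with early stopping
#' (patience three) on validation mean AUC, binary cross entropy, initial
#' learning rate 1e-4 reduced by a factor of 10 after each epoch, with an
#' Adam-style adaptive optimizer.
#'
#' @param epochs Number of epochs.
#' @param patience Early-stop patience (epochs without val-AUC improvement).
#' @param lr0 Initial learning rate.
#' @param lr_decay Per-epoch multiplicative decay.
#' @param batch_size Mini-batch size.
#' @param fractions Train/val/test split fractions (must sum to 1).
#' @return A `fine_tune_config`.
#' @export
fine_tune_config <- function(epochs = 5L, patience = 3L, lr0 = 1e-4,
                             lr_decay = 0.1, batch_size = 16L,
                             fractions = c(0.7, 0.1, 0.2)) {
  stopifnot(epochs >= 1L, patience >= 1L, lr0 > 0,
            abs(sum(fractions) - 1) < 1e-8)
  structure(list(epochs = as.integer(epochs), patience = as.integer(patience),
                 lr0 = lr0, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size), fractions = fractions),
            class = "fine_tune_config")
}

#' Replace a fixture CNN's classification head
#'
#' Installs a freshly initialized dense layer sized to a new set of target
#' labels, keeping all convolutional weights.
#'
#' @param model A `fixture_cnn`.
#' @param n_labels New number of outputs.
#' @param seed Seed for head initialization (random init only).
#' @param label_names Optional target label names.
#' @param init `"zero"` starts the new head at exactly zero — the first
#'   optimizer steps then move it along the class-difference direction of
#'   the frozen-quality pretrained features, which is what a small
#'   fine-tuning learning rate needs; `"random"` uses the same Gaussian
#'   init as [build_fixture_cnn()].
#' @return The model with a new head.
#' @export
replace_head <- function(model, n_labels, seed = 1L, label_names = NULL,
                         init = c("zero", "random")) {
  init <- match.arg(init)
  stopifnot(inherits(model, "fixture_cnn"), n_labels >= 1L)
  cf <- model$channels[length(model$channels)]
  set.seed(as.integer(seed))
  W <- if (init == "zero") {
    matrix(0, cf, n_labels)
  } else {
    matrix(stats::rnorm(cf * n_labels, sd = sqrt(1 / cf)), cf, n_labels)
  }
  model$head <- list(W = W, b = numeric(n_labels))
  model$n_labels <- as.integer(n_labels)
  model$label_names <- label_names
  model
}

#' Fine-tune a pretrained fixture CNN on a target task
#'
#' Replaces the classification head with a randomly initialized dense layer
#' sized to the target labels, then trains all weights per the
#' configuration, returning the epoch checkpoint with the best validation
#' mean AUC.
#'
#' @param model A pretrained `fixture_cnn`.
#' @param train,val Lists `list(images =, labels =)`; the validation set must
#'   be nonempty.
#' @param cfg A [fine_tune_config()].
#' @param seed Integer seed (head init and batch shuffling).
#' @return List `model` (best checkpoint), `history`, `best_epoch`.
#' @export
fine_tune <- function(model, train, val, cfg = fine_tune_config(),
                      seed = 1L) {
  stopifnot(inherits(cfg, "fine_tune_config"))
  if (is.null(val) || length(val$images) == 0L) {
    stop("fine-tuning requires a nonempty validation set", call. = FALSE)
  }
  labels <- as.matrix(train$labels)
  model <- replace_head(model, ncol(labels), seed = seed,
                        label_names = colnames(labels))
  train_cnn(model, train$images, labels,
            epochs = cfg$epochs, lr = cfg$lr0, lr_decay = cfg$lr_decay,
            batch_size = cfg$batch_size,
            val = list(images = val$images, labels = as.matrix(val$labels)),
            patience = cfg$patience, seed = seed)
}
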