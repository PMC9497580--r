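# End-to-end experiment orchestration: generate a synthetic source cohort,
# pretrain K fixture CNNs on it, then compare the four transfer strategies
# on a synthetic target cohort — direct mapped inference, stacking,
# tree classifiers on embeddings, and fine-tuning — each combined with
# simple and entropy-weighted ensembling and scored by per-label AUC.

#' Default source/target cohort pair for the synthetic experiment
#'
#' The source domain carries five fine-grained labels; the target domain
#' carries three coarse labels, each the union of source findings that share
#' an image region (so a source-trained detector transfers). Geometries are
#' region-disjoint across target labels.
#'
#' @param side Image side in pixels.
#' @param n_source,n_target Cohort sizes.
#' @param seed Integer seed (fanned out per cohort).
#' @return List with `source_spec`, `target_spec`, `mapping`.
#' @export
default_cohorts <- function(side = 32L, n_source = 240L, n_target = 240L,
                            seed = 1L) {
  q <- side / 4
  geom_src <- list(
    cardiomegaly = signature_geometry("disc", c(q, q), max(3, round(side / 8)), 1),
    enlarged_cardiomediastinum = signature_geometry("bar", c(q, q),
                                                    max(3, round(side / 8)), 0.8),
    lung_opacity = signature_geometry("disc", c(q, 3 * q), max(3, round(side / 8)), 1),
    consolidation = signature_geometry("bar", c(q, 3 * q), max(3, round(side / 8)), 0.8),
    pleural_effusion = signature_geometry("disc", c(3 * q, q), max(3, round(side / 8)), 1)
  )
  source_spec <- synthetic_image_spec(
    height = side, width = side, n_images = n_source,
    label_names = names(geom_src),
    prevalence = c(0.3, 0.25, 0.3, 0.25, 0.3),
    geometry = geom_src, noise_sd = 0.15, landmark_prob = 0.05,
    seed = child_seed(seed, "images", 1L)
  )
  geom_tgt <- list(
    cardiac = geom_src$cardiomegaly,
    lung = geom_src$lung_opacity,
    pleura = geom_src$pleural_effusion
  )
  target_spec <- synthetic_image_spec(
    height = side, width = side, n_images = n_target,
    label_names = names(geom_tgt),
    prevalence = c(0.25, 0.45, 0.3),
    geometry = geom_tgt, noise_sd = 0.15, landmark_prob = 0.05,
    seed = child_seed(seed, "images", 2L)
  )
  mapping <- label_mapping(list(
    cardiac = c("cardiomegaly", "enlarged_cardiomediastinum"),
    lung = c("lung_opacity", "consolidation"),
    pleura = "pleural_effusion"
  ), source_labels = names(geom_src))
  list(source_spec = source_spec, target_spec = target_spec,
       mapping = mapping)
}

#' Experiment configuration
#'
#' @param seed Master seed; every stage derives a child seed from it.
#' @param side Image side in pixels.
#' @param n_source,n_target Cohort sizes.
#' @param n_models Number K of fixture base networks.
#' @param channels List of per-network conv-channel vectors (recycled to K);
#'   different widths stand in for heterogeneous architectures.
#' @param pretrain_epochs,pretrain_lr Source-task training schedule.
#' @param strategies Subset of `c("mapped", "stacking", "embeddings",
#'   "finetune")`.
#' @param ensembles Subset of `c("simple", "entropy")`.
#' @param tree_kinds Tree families for the embeddings strategy.
#' @param tree_grid A [tree_grid_config()] template used (with each kind)
#'   for the embeddings strategy; `NULL` for a small default grid.
#' @param finetune A [fine_tune_config()].
#' @param fractions Target train/val/test fractions.
#' @param outdir Output directory (created); `NULL` writes nothing.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(seed = 1L, side = 32L, n_source = 240L,
                              n_target = 240L, n_models = 3L,
                              channels = list(c(8L, 16L, 16L),
                                              c(6L, 12L, 12L),
                                              c(8L, 12L, 16L)),
                              pretrain_epochs = 6L, pretrain_lr = 5e-3,
                              strategies = c("mapped", "stacking",
                                             "embeddings", "finetune"),
                              ensembles = c("simple", "entropy"),
                              tree_kinds = c("DT", "RF", "XRT"),
                              tree_grid = NULL,
                              finetune = fine_tune_config(),
                              fractions = c(0.7, 0.1, 0.2),
                              outdir = NULL) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  ensembles <- match.arg(ensembles, several.ok = TRUE)
  tree_kinds <- match.arg(tree_kinds, c("DT", "RF", "XRT"), several.ok = TRUE)
  stopifnot(length(strategies) >= 1L, n_models >= 1L,
            abs(sum(fractions) - 1) < 1e-8)
  structure(list(seed = as.integer(seed), side = as.integer(side),
                 n_source = as.integer(n_source),
                 n_target = as.integer(n_target),
                 n_models = as.integer(n_models),
                 channels = rep_len(channels, n_models),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 pretrain_lr = pretrain_lr,
                 strategies = strategies, ensembles = ensembles,
                 tree_kinds = tree_kinds, tree_grid = tree_grid,
                 finetune = finetune, fractions = fractions,
                 outdir = outdir),
            class = "experiment_config")
}

# Preprocess a list of raw intensity images for the fixture networks:
# clip -> unit scale -> resize/stack -> standardize with (0.5, 0.5).
.preprocess_all <- function(images, side) {
  lapply(images, preprocess_image, side = side, means = 0.5, sds = 0.5)
}

.auc_row <- function(strategy, model, ensemble, res) {
  as.data.frame(c(list(strategy = strategy, model = model,
                       ensemble = ensemble),
                  as.list(round(res$auc, 6)),
                  list(mean = round(res$mean_auc, 6))))
}

#' Run the full synthetic transfer-learning comparison
#'
#' Generates source and target cohorts, pretrains K fixture CNNs on the
#' source task, and evaluates the configured transfer strategies on the
#' held-out target test split. Per-strategy failures are caught and
#' reported without aborting the rest. When `cfg$outdir` is set, the
#' comparison grid (CSV + JSON), per-strategy prediction CSVs, the split
#' manifest and the config are written there.
#'
#' @param cfg An [experiment_config()].
#' @return A `comparison_report`: list with `grid` (data frame of per-label
#'   AUCs and means), `predictions` (named list of test-score matrices),
#'   `errors`, `split`, `timings`, `config`.
#' @export
run_experiment <- function(cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name, since) {
    timings[[name]] <<- round(proc.time()[["elapsed"]] - since, 2)
  }
  co <- default_cohorts(cfg$side, cfg$n_source, cfg$n_target, cfg$seed)
  src <- generate_images(co$source_spec)
  tgt <- generate_images(co$target_spec)
  x_src <- .preprocess_all(src$images, cfg$side)
  x_tgt <- .preprocess_all(tgt$images, cfg$side)
  tick("data", t0)

  t1 <- proc.time()[["elapsed"]]
  models <- vector("list", cfg$n_models)
  for (k in seq_len(cfg$n_models)) {
    net <- build_fixture_cnn(
      n_labels = length(co$source_spec$label_names),
      seed = child_seed(cfg$seed, "cnn", k),
      input_shape = c(cfg$side, cfg$side, 3L),
      channels = cfg$channels[[k]],
      label_names = co$source_spec$label_names
    )
    models[[k]] <- train_cnn(net, x_src, src$labels,
                             epochs = cfg$pretrain_epochs,
                             lr = cfg$pretrain_lr,
                             seed = child_seed(cfg$seed, "cnn", 100L + k))$model
  }
  tick("pretrain", t1)

  split <- stratified_split(tgt$labels, cfg$fractions,
                            seed = child_seed(cfg$seed, "split"))
  idx_fit <- sort(c(split$train, if (!is.null(split$val)) split$val))
  idx_test <- split$test
  y_test <- tgt$labels[idx_test, , drop = FALSE]

  grid <- NULL
  preds_out <- list()
  errors <- list()
  add_rows <- function(rows) grid <<- rbind(grid, rows)
  ens_methods <- sub("^entropy$", "entropy", cfg$ensembles)

  # per-model mapped predictions on an index set
  mapped_on <- function(idx) {
    arr <- array(NA_real_,
                 c(cfg$n_models, length(co$mapping$target_labels), length(idx)),
                 dimnames = list(paste0("net", seq_len(cfg$n_models)),
                                 co$mapping$target_labels, NULL))
    for (k in seq_len(cfg$n_models)) {
      p <- predict(models[[k]], x_tgt[idx])
      arr[k, , ] <- t(map_predictions(p, co$mapping))
    }
    arr
  }
  mapped_test <- mapped_on(idx_test)

  run_stage <- function(name, fun) {
    t <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
    tick(name, t)
    res
  }

  ensemble_and_report <- function(strategy, arr) {
    for (m in ens_methods) {
      sc <- ensemble_scores(arr, if (m == "simple") "simple" else "entropy")
      res <- evaluate_predictions(sc, y_test)
      add_rows(.auc_row(strategy, "ensemble", m, res))
      preds_out[[paste(strategy, m, sep = "_")]] <<- sc
    }
  }

  if ("mapped" %in% cfg$strategies) {
    run_stage("mapped", function() {
      for (k in seq_len(cfg$n_models)) {
        sc <- t(mapped_test[k, , , drop = TRUE])
        if (dim(mapped_test)[2L] == 1L) sc <- matrix(mapped_test[k, , ], ncol = 1L)
        colnames(sc) <- co$mapping$target_labels
        add_rows(.auc_row("mapped", paste0("net", k), "none",
                          evaluate_predictions(sc, y_test)))
      }
      ensemble_and_report("mapped", mapped_test)
      TRUE
    })
  }

  if ("stacking" %in% cfg$strategies) {
    run_stage("stacking", function() {
      mapped_fit <- mapped_on(idx_fit)
      st <- fit_stacking(mapped_fit, tgt$labels[idx_fit, , drop = FALSE],
                         seed = child_seed(cfg$seed, "stacking"))
      sc <- predict(st, mapped_test)
      res <- evaluate_predictions(sc, y_test)
      add_rows(.auc_row("stacking", "RF-meta", "none", res))
      preds_out[["stacking"]] <<- sc
      TRUE
    })
  }

  if ("embeddings" %in% cfg$strategies) {
    run_stage("embeddings", function() {
      emb_fit <- lapply(models, extract_embeddings, images = x_tgt[idx_fit])
      emb_test <- lapply(models, extract_embeddings, images = x_tgt[idx_test])
      for (kind in cfg$tree_kinds) {
        tg <- cfg$tree_grid
        tg_kind <- if (is.null(tg)) {
          tree_grid_config(kind, max_depth = c(3, 10),
                           min_samples_leaf = c(1, 4),
                           min_samples_split = 2, criterion = "gini",
                           n_estimators = 100, k_folds = 3L,
                           seed = child_seed(cfg$seed, "trees"))
        } else {
          tree_grid_config(kind, tg$max_depth, tg$min_samples_leaf,
                           tg$min_samples_split, tg$criterion,
                           tg$n_estimators, tg$k_folds,
                           seed = child_seed(cfg$seed, "trees"))
        }
        arr <- array(NA_real_,
                     c(cfg$n_models, ncol(y_test), length(idx_test)),
                     dimnames = list(paste0("net", seq_len(cfg$n_models)),
                                     colnames(y_test), NULL))
        for (k in seq_len(cfg$n_models)) {
          fit <- fit_tree_classifier(emb_fit[[k]],
                                     tgt$labels[idx_fit, , drop = FALSE],
                                     tg_kind)
          arr[k, , ] <- t(predict(fit, emb_test[[k]]))
        }
        ensemble_and_report(paste0("embeddings_", kind), arr)
      }
      TRUE
    })
  }

  if ("finetune" %in% cfg$strategies) {
    run_stage("finetune", function() {
      if (is.null(split$val)) stop("fine-tuning needs a validation split")
      arr <- array(NA_real_, c(cfg$n_models, ncol(y_test), length(idx_test)),
                   dimnames = list(paste0("net", seq_len(cfg$n_models)),
                                   colnames(y_test), NULL))
      for (k in seq_len(cfg$n_models)) {
        ft <- fine_tune(
          models[[k]],
          train = list(images = x_tgt[split$train],
                       labels = tgt$labels[split$train, , drop = FALSE]),
          val = list(images = x_tgt[split$val],
                     labels = tgt$labels[split$val, , drop = FALSE]),
          cfg = cfg$finetune,
          seed = child_seed(cfg$seed, "finetune", k)
        )
        p <- predict(ft$model, x_tgt[idx_test])
        colnames(p) <- colnames(y_test)
        arr[k, , ] <- t(p)
        add_rows(.auc_row("finetune", paste0("net", k), "none",
                          evaluate_predictions(p, y_test)))
      }
      ensemble_and_report("finetune", arr)
      TRUE
    })
  }

  timings$total <- round(proc.time()[["elapsed"]] - t0, 2)
  report <- structure(
    list(grid = grid, predictions = preds_out, errors = errors,
         split = split, timings = timings, config = cfg,
         test_labels = y_test),
    class = "comparison_report"
  )
  if (!is.null(cfg$outdir)) save_report(report, cfg$outdir)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$grid, row.names = FALSE)
  if (length(x$errors)) {
    cat("stage errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n")
  }
  invisible(x)
}

# ---- label / report I/O ----------------------------------------------------

#' Read a multi-label annotation CSV
#'
#' Expects UTF-8 CSV with a header, an `image_id` column, and one 0/1
#' column per label.
#'
#' @param path CSV file.
#' @param label_names Optional expected label names; unknown or missing
#'   labels raise an error.
#' @return Binary matrix with `image_id` rownames.
#' @export
load_labels <- function(path, label_names = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty label file: ", path, call. = FALSE)
  if (!"image_id" %in% names(df)) {
    stop("label file lacks an `image_id` column", call. = FALSE)
  }
  labs <- setdiff(names(df), "image_id")
  if (!is.null(label_names)) {
    missing <- setdiff(label_names, labs)
    unknown <- setdiff(labs, label_names)
    if (length(missing)) stop("missing label column(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
    if (length(unknown)) stop("unknown label column(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    labs <- label_names
  }
  m <- as.matrix(df[, labs, drop = FALSE])
  if (!all(m %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df$image_id)
  m
}

#' Write a multi-label matrix as CSV
#'
#' @param labels Binary matrix with optional rownames as image ids.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
save_labels <- function(labels, path) {
  ids <- rownames(labels)
  if (is.null(ids)) ids <- sprintf("img%04d", seq_len(nrow(labels)))
  df <- data.frame(image_id = ids, labels, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a comparison report to disk
#'
#' Writes `report.csv` (the AUC grid), `report.json` (grid, timings, errors,
#' seeds), `split.csv` (the split manifest), `config.yaml`, and one
#' `predictions_<strategy>.csv` per stored prediction set.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$grid, file.path(dir, "report.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(grid = report$grid, timings = report$timings,
         errors = report$errors, seed = report$config$seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  split_df <- do.call(rbind, lapply(names(report$split), function(p) {
    data.frame(part = p, index = report$split[[p]])
  }))
  utils::write.csv(split_df, file.path(dir, "split.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- report$config
  cfg_plain <- list(seed = cfg$seed, side = cfg$side,
                    n_source = cfg$n_source, n_target = cfg$n_target,
                    n_models = cfg$n_models,
                    strategies = cfg$strategies, ensembles = cfg$ensembles,
                    tree_kinds = cfg$tree_kinds, fractions = cfg$fractions)
  yaml::write_yaml(cfg_plain, file.path(dir, "config.yaml"))
  for (nm in names(report$predictions)) {
    sc <- report$predictions[[nm]]
    df <- data.frame(sample = seq_len(nrow(sc)),
                     format(as.data.frame(sc), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE)
    utils::write.csv(df, file.path(dir, paste0("predictions_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
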