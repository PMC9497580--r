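# Synthetic-data generators: radiograph-like images whose labels are caused
# by geometric signatures at known locations (so localization is verifiable),
# classifier prediction matrices and embedding matrices with controlled
# per-label signal, and the specs describing them. Rare saturated "landmark"
# pixel clusters emulate the acquisition artifacts that quantile clipping is
# meant to remove.

#' Describe a label-linked geometric signature
#'
#' @param shape `"disc"`, `"bar"` or `"arc"` (a ring segment).
#' @param center `c(row, col)` center in pixels.
#' @param size Radius (disc/arc) or half-width (bar) in pixels.
#' @param intensity Additive intensity lift inside the shape.
#' @return A `signature_geometry` list.
#' @export
signature_geometry <- function(shape = c("disc", "bar", "arc"),
                               center, size, intensity = 1) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 2L, size >= 1, intensity > 0)
  structure(list(shape = shape, center = as.numeric(center),
                 size = as.numeric(size), intensity = as.numeric(intensity)),
            class = "signature_geometry")
}

# Rasterize a signature into a logical mask.
.signature_mask <- function(geom, height, width) {
  r <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  dr <- r - geom$center[1L]
  dc <- cc - geom$center[2L]
  switch(geom$shape,
    disc = dr^2 + dc^2 <= geom$size^2,
    bar = abs(dr) <= max(1, geom$size / 3) & abs(dc) <= geom$size,
    arc = {
      rad <- sqrt(dr^2 + dc^2)
      ang <- atan2(dr, dc)
      rad >= 0.6 * geom$size & rad <= geom$size & ang >= 0 & ang <= pi / 2
    }
  )
}

# Default disjoint placement: labels on a ceiling(L/2) x 2 grid of cells.
.default_geometry <- function(label_names, height, width) {
  L <- length(label_names)
  ncell <- max(2L, ceiling(L / 2) * 2L)
  nrows <- ncell %/% 2L
  size <- max(3, round(min(height / (2 * nrows), width / 4) * 0.55))
  shapes <- c("disc", "bar", "arc")
  geoms <- vector("list", L)
  names(geoms) <- label_names
  for (j in seq_len(L)) {
    gr <- (j - 1L) %% nrows
    gc <- (j - 1L) %/% nrows
    center <- c((gr + 0.5) * height / nrows, (gc + 0.5) * width / 2)
    geoms[[j]] <- signature_geometry(shapes[(j - 1L) %% 3L + 1L],
                                     center = round(center), size = size,
                                     intensity = 1)
  }
  geoms
}

#' Specification of a synthetic multi-label image cohort
#'
#' Images are background noise plus, for each positive label, an additive
#' geometric signature at a known fixed location; labels are independent
#' Bernoulli draws with per-label prevalence. With probability
#' `landmark_prob` an image also receives a tiny saturated-intensity pixel
#' cluster (at most 0.02% of pixels, always at least one pixel) whose
#' intensity is ten times the 99th percentile of the rest of the image — the
#' artifact the 0.9995-quantile clip is designed to remove.
#'
#' Default label names and prevalences mirror the abnormality frequencies of
#' a ~941-image hospital chest-radiograph cohort (cardiac 9.9%, lung 45.4%,
#' pneumothorax 4%, pleura 14.3%, bone 14.6%, device 15.6%).
#'
#' @param height,width Image size in pixels (>= 8).
#' @param n_images Number of images.
#' @param label_names Ordered label names.
#' @param prevalence Per-label positive probability in `[0, 1]`.
#' @param geometry Named list of [signature_geometry()] per label, or `NULL`
#'   for a default disjoint grid placement.
#' @param background Mean background intensity.
#' @param noise_sd Background noise standard deviation (intensity units).
#' @param landmark_prob Probability an image gets a landmark cluster.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(height = 64L, width = 64L, n_images = 200L,
                                 label_names = c("cardiac", "lung", "pnx",
                                                 "pleura", "bone", "device"),
                                 prevalence = c(0.099, 0.454, 0.040,
                                                0.143, 0.146, 0.156),
                                 geometry = NULL,
                                 background = 0.25, noise_sd = 0.15,
                                 landmark_prob = 0.05, seed = 1L) {
  stopifnot(height >= 8L, width >= 8L, n_images >= 1L,
            length(prevalence) == length(label_names))
  .assert_prob(prevalence, "prevalence")
  .assert_scalar_in(landmark_prob, 0, 1, "landmark_prob")
  if (is.null(geometry)) geometry <- .default_geometry(label_names, height, width)
  stopifnot(setequal(names(geometry), label_names))
  for (nm in label_names) {
    g <- geometry[[nm]]
    if (g$center[1L] - g$size < 1 || g$center[1L] + g$size > height ||
        g$center[2L] - g$size < 1 || g$center[2L] + g$size > width) {
      stop(sprintf("signature region for label '%s' exceeds image bounds", nm),
           call. = FALSE)
    }
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_images = as.integer(n_images),
                 label_names = label_names,
                 prevalence = stats::setNames(prevalence, label_names),
                 geometry = geometry[label_names],
                 background = background, noise_sd = noise_sd,
                 landmark_prob = landmark_prob, seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

#' Generate a synthetic image cohort with known localization ground truth
#'
#' @param spec A [synthetic_image_spec()].
#' @return List with `images` (list of nonnegative intensity matrices),
#'   `labels` (binary `n_images x L` matrix), `truth_masks` (per image, a
#'   named list of logical matrices marking exactly the signature pixels;
#'   all-`FALSE` for negative labels), and `landmarks` (logical vector:
#'   which images received a saturated landmark cluster).
#' @export
generate_images <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  set.seed(spec$seed)
  n <- spec$n_images
  L <- length(spec$label_names)
  labels <- matrix(
    stats::rbinom(n * L, 1L, rep(spec$prevalence, each = n)), n, L,
    dimnames = list(NULL, spec$label_names)
  )
  masks <- lapply(spec$label_names, function(nm) {
    .signature_mask(spec$geometry[[nm]], spec$height, spec$width)
  })
  names(masks) <- spec$label_names
  landmark_px <- max(1L, floor(2e-4 * spec$height * spec$width))
  has_landmark <- stats::runif(n) < spec$landmark_prob
  empty <- matrix(FALSE, spec$height, spec$width)
  images <- vector("list", n)
  truth_masks <- vector("list", n)
  for (i in seq_len(n)) {
    img <- pmax(spec$background +
                  matrix(stats::rnorm(spec$height * spec$width,
                                      sd = spec$noise_sd),
                         spec$height, spec$width), 0)
    tm <- vector("list", L)
    names(tm) <- spec$label_names
    for (j in seq_len(L)) {
      if (labels[i, j] == 1L) {
        m <- masks[[j]]
        img[m] <- img[m] + spec$geometry[[j]]$intensity
        tm[[j]] <- m
      } else {
        tm[[j]] <- empty
      }
    }
    if (has_landmark[i]) {
      q99 <- stats::quantile(img, 0.99, names = FALSE)
      r0 <- sample.int(spec$height - 1L, 1L)
      c0 <- sample.int(spec$width - 1L, 1L)
      # fill a tiny cluster row-wise from the anchor pixel
      pos <- cbind(r0 + c(0L, 0L, 1L, 1L), c0 + c(0L, 1L, 0L, 1L))
      pos <- pos[seq_len(landmark_px), , drop = FALSE]
      # 12x the 99th percentile: safely above the 10x saturation floor
      img[pos] <- 12 * max(q99, spec$background)
    }
    images[[i]] <- img
    truth_masks[[i]] <- tm
  }
  list(images = images, labels = labels, truth_masks = truth_masks,
       landmarks = has_landmark)
}

#' Single-label "blob task" image spec
#'
#' A disc of fixed size in a fixed quadrant with 50% prevalence — the
#' canonical localization benchmark used in the training and Grad-CAM
#' recovery checks.
#'
#' @param n_images Number of images.
#' @param side Image side in pixels.
#' @param seed Integer seed.
#' @param prevalence Positive probability.
#' @return A [synthetic_image_spec()] with a single `"blob"` label.
#' @export
blob_task_spec <- function(n_images = 400L, side = 32L, seed = 1L,
                           prevalence = 0.5) {
  r <- max(3, round(side / 7))
  synthetic_image_spec(
    height = side, width = side, n_images = n_images,
    label_names = "blob", prevalence = prevalence,
    geometry = list(blob = signature_geometry(
      "disc", center = round(c(side / 4, side / 4)), size = r, intensity = 1
    )),
    noise_sd = 0.15, landmark_prob = 0.05, seed = seed
  )
}

# ---- prediction matrices ---------------------------------------------------

#' Specification of synthetic classifier prediction matrices
#'
#' Emulates the outputs of a pool of probabilistic classifiers of controlled
#' skill. Each classifier k sees a latent score `z ~ N(skill_k * y, 1)`; in
#' `"calibrated"` mode the emitted probability is the exact posterior under
#' that model (`plogis(skill*z - skill^2/2)`), `"overconfident"` sharpens the
#' calibrated logit sixfold so scores pile up near 0 and 1, and
#' `"uninformative"` emits scores near 0.5 regardless of the label.
#'
#' @param n_classifiers Number of classifiers K.
#' @param skill Per-classifier separation (recycled to length K). `0` gives
#'   chance-level scores; `Inf` gives perfect separation.
#' @param calibration `"calibrated"`, `"overconfident"` or `"uninformative"`.
#' @param seed Integer seed.
#' @return A `synthetic_prediction_spec`.
#' @export
synthetic_prediction_spec <- function(n_classifiers = 3L, skill = 2,
                                      calibration = c("calibrated",
                                                      "overconfident",
                                                      "uninformative"),
                                      seed = 1L) {
  calibration <- match.arg(calibration)
  stopifnot(n_classifiers >= 1L, all(skill >= 0))
  structure(list(n_classifiers = as.integer(n_classifiers),
                 skill = rep_len(skill, n_classifiers),
                 calibration = calibration, seed = as.integer(seed)),
            class = "synthetic_prediction_spec")
}

#' Generate per-sample prediction matrices
#'
#' @param spec A [synthetic_prediction_spec()].
#' @param labels Binary `n x L` matrix of ground-truth labels.
#' @return Array `(K, L, n)` of probabilities in `[0, 1]`, with classifier,
#'   label and sample dimnames.
#' @export
generate_predictions <- function(spec, labels) {
  stopifnot(inherits(spec, "synthetic_prediction_spec"))
  labels <- as.matrix(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  set.seed(spec$seed)
  n <- nrow(labels)
  L <- ncol(labels)
  K <- spec$n_classifiers
  out <- array(NA_real_, c(K, L, n),
               dimnames = list(paste0("clf", seq_len(K)),
                               colnames(labels), NULL))
  for (k in seq_len(K)) {
    s <- spec$skill[k]
    for (j in seq_len(L)) {
      y <- labels[, j]
      if (spec$calibration == "uninformative") {
        p <- stats::plogis(stats::rnorm(n, 0, 0.2))
      } else if (is.infinite(s)) {
        p <- as.numeric(y)
      } else {
        z <- s * y + stats::rnorm(n)
        u <- s * z - s^2 / 2
        if (spec$calibration == "overconfident") u <- 6 * u
        p <- stats::plogis(u)
      }
      out[k, j, ] <- p
    }
  }
  out
}

# ---- embedding matrices ----------------------------------------------------

#' Specification of synthetic embedding matrices
#'
#' Gaussian feature matrices in which each label shifts the mean of its own
#' small set of informative dimensions for positive samples — a stand-in for
#' pooled convolutional (GAP) embeddings with controllable linear signal.
#'
#' @param dim Embedding dimension d.
#' @param n_informative Informative dimensions per label (used when
#'   `informative` is `NULL`; consecutive disjoint blocks are assigned).
#' @param informative Optional named list of informative-dimension index
#'   vectors per label (may overlap if you say so explicitly).
#' @param effect_size Mean shift on informative dimensions for positives.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param seed Integer seed.
#' @return A `synthetic_embedding_spec`.
#' @export
synthetic_embedding_spec <- function(dim = 16L, n_informative = 3L,
                                     informative = NULL, effect_size = 2,
                                     noise_sd = 1, seed = 1L) {
  stopifnot(dim >= 1L, effect_size >= 0, noise_sd > 0)
  structure(list(dim = as.integer(dim),
                 n_informative = as.integer(n_informative),
                 informative = informative,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_embedding_spec")
}

#' Generate an embedding matrix with label-linked informative dimensions
#'
#' @param spec A [synthetic_embedding_spec()].
#' @param labels Binary `n x L` matrix.
#' @return `n x d` matrix; attribute `"informative"` records the per-label
#'   dimension sets actually used.
#' @export
generate_embeddings <- function(spec, labels) {
  stopifnot(inherits(spec, "synthetic_embedding_spec"))
  labels <- as.matrix(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  L <- ncol(labels)
  info <- spec$informative
  if (is.null(info)) {
    if (L * spec$n_informative > spec$dim) {
      stop("dim too small for disjoint informative sets", call. = FALSE)
    }
    info <- lapply(seq_len(L), function(j) {
      (j - 1L) * spec$n_informative + seq_len(spec$n_informative)
    })
    names(info) <- colnames(labels)
  }
  stopifnot(all(unlist(info) >= 1L), all(unlist(info) <= spec$dim))
  set.seed(spec$seed)
  n <- nrow(labels)
  X <- matrix(stats::rnorm(n * spec$dim, 0, spec$noise_sd), n, spec$dim)
  for (j in seq_len(L)) {
    pos <- labels[, j] == 1L
    X[pos, info[[j]]] <- X[pos, info[[j]]] + spec$effect_size
  }
  colnames(X) <- paste0("e", seq_len(spec$dim))
  attr(X, "informative") <- info
  X
}
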