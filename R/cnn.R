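# Small convolutional-network engine: im2col convolution, ReLU, 2x2 max
# pooling, global average pooling (GAP) and a dense sigmoid head, trained by
# Adam on binary cross entropy. Fixture networks built here expose everything
# the rest of the package needs from a CNN: per-label probabilities, the final
# convolutional feature maps, the GAP embedding vector, and gradients of any
# output logit with respect to the final maps.

# ---- batch helpers ---------------------------------------------------------

# Batches are arrays (H, W, C, N). A single image may come in as a matrix
# (H, W), an (H, W, C) array, or a processed_image.
.as_batch <- function(images) {
  if (is.list(images) && !is.array(images)) {
    images <- lapply(images, function(im) {
      im <- unclass(im)
      if (is.matrix(im)) array(im, c(dim(im), 1L)) else im
    })
    d <- dim(images[[1L]])
    out <- array(0, c(d, length(images)))
    for (n in seq_along(images)) {
      if (!identical(dim(images[[n]]), d)) stop("images differ in shape")
      out[, , , n] <- images[[n]]
    }
    return(out)
  }
  images <- unclass(images)
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L, 1L))
  if (length(dim(images)) == 3L) images <- array(images, c(dim(images), 1L))
  stopifnot(length(dim(images)) == 4L)
  images
}

.pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  out[p + seq_len(d[1L]), p + seq_len(d[2L]), , ] <- x
  out
}

# Patch-extraction index for one channel of one padded image: rows index the
# output pixel (column-major), columns the k x k kernel offset (rows fastest).
.im2col_index <- function(Hp, Wp, k) {
  Ho <- Hp - k + 1L
  Wo <- Wp - k + 1L
  base <- outer(seq_len(Ho), (seq_len(Wo) - 1L) * Hp, `+`)
  off <- outer(seq_len(k) - 1L, (seq_len(k) - 1L) * Hp, `+`)
  outer(as.vector(base), as.vector(off), `+`)
}

# xp: padded batch (Hp, Wp, C, N) -> matrix (Ho*Wo*N) x (k*k*C); row blocks
# are images, columns are kernel offsets (fastest) within input channel.
.im2col <- function(xp, k) {
  d <- dim(xp)
  Hp <- d[1L]; Wp <- d[2L]; C <- d[3L]; N <- d[4L]
  Ho <- Hp - k + 1L
  Wo <- Wp - k + 1L
  idx <- .im2col_index(Hp, Wp, k)
  iv <- as.vector(outer(idx, (seq_len(C) - 1L) * (Hp * Wp), `+`))
  X <- matrix(0, Ho * Wo * N, k * k * C)
  stride <- Hp * Wp * C
  for (n in seq_len(N)) {
    X[(n - 1L) * Ho * Wo + seq_len(Ho * Wo), ] <- xp[iv + (n - 1L) * stride]
  }
  X
}

.conv_forward <- function(x, W, b, k) {
  p <- (k - 1L) %/% 2L
  xp <- .pad_hw(x, p)
  X <- .im2col(xp, k)
  Y <- X %*% W
  Y <- sweep(Y, 2L, b, `+`)
  d <- dim(x)
  y <- aperm(array(Y, c(d[1L], d[2L], d[4L], ncol(W))), c(1L, 2L, 4L, 3L))
  list(y = y, X = X, in_dim = d)
}

.conv_backward <- function(dy, cache, W, k) {
  d <- cache$in_dim
  H <- d[1L]; Wd <- d[2L]; C <- d[3L]; N <- d[4L]
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- Wd + 2L * p
  Cout <- dim(dy)[3L]
  dY <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), H * Wd * N, Cout)
  dW <- crossprod(cache$X, dY)
  db <- colSums(dY)
  dXc <- dY %*% t(W)
  dxp <- array(0, c(Hp, Wp, C, N))
  for (q in seq_len(k * k)) {
    kr <- (q - 1L) %% k
    kc <- (q - 1L) %/% k
    block <- dXc[, q + (seq_len(C) - 1L) * (k * k), drop = FALSE]
    barr <- aperm(array(block, c(H, Wd, N, C)), c(1L, 2L, 4L, 3L))
    rr <- kr + seq_len(H)
    cc <- kc + seq_len(Wd)
    dxp[rr, cc, , ] <- dxp[rr, cc, , , drop = FALSE] + barr
  }
  dx <- dxp[p + seq_len(H), p + seq_len(Wd), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

.maxpool_forward <- function(x) {
  d <- dim(x)
  stopifnot(d[1L] %% 2L == 0L, d[2L] %% 2L == 0L)
  i1 <- seq(1L, d[1L], 2L); j1 <- seq(1L, d[2L], 2L)
  x11 <- x[i1, j1, , , drop = FALSE]
  x21 <- x[i1 + 1L, j1, , , drop = FALSE]
  x12 <- x[i1, j1 + 1L, , , drop = FALSE]
  x22 <- x[i1 + 1L, j1 + 1L, , , drop = FALSE]
  m <- pmax(x11, x21, x12, x22)
  w1 <- x11 == m
  w2 <- (x21 == m) & !w1
  w3 <- (x12 == m) & !(w1 | w2)
  w4 <- (x22 == m) & !(w1 | w2 | w3)
  list(y = m, w = list(w1, w2, w3, w4), in_dim = d)
}

.maxpool_backward <- function(dy, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  i1 <- seq(1L, d[1L], 2L); j1 <- seq(1L, d[2L], 2L)
  w <- cache$w
  dx[i1, j1, , ] <- dy * w[[1L]]
  dx[i1 + 1L, j1, , ] <- dy * w[[2L]]
  dx[i1, j1 + 1L, , ] <- dy * w[[3L]]
  dx[i1 + 1L, j1 + 1L, , ] <- dy * w[[4L]]
  dx
}

.gap_forward <- function(fmaps) {
  d <- dim(fmaps)
  t(matrix(colMeans(matrix(fmaps, d[1L] * d[2L], d[3L] * d[4L])), d[3L], d[4L]))
}

.gap_backward <- function(dgap, fmap_dim) {
  hw <- fmap_dim[1L] * fmap_dim[2L]
  array(rep(as.vector(t(dgap)) / hw, each = hw), fmap_dim)
}

# ---- model construction ----------------------------------------------------

#' Build a small fixture convolutional network
#'
#' Constructs a randomly initialized CNN with 2-3 convolution blocks
#' (3x3 "same" convolution + ReLU, all but the last followed by 2x2 max
#' pooling), a global average pooling (GAP) layer, and a dense layer with one
#' sigmoid output per label. The final convolutional feature maps feed GAP
#' directly, so the network has the classical CAM-compatible head topology.
#'
#' @param n_labels Number of sigmoid outputs.
#' @param seed Integer seed for weight initialization.
#' @param input_shape `c(height, width, channels)` of expected inputs.
#'   Height and width must be divisible by `2^(length(channels) - 1)`.
#' @param channels Output channels per conv block; the last entry is the
#'   embedding dimension (GAP vector length).
#' @param label_names Optional character vector of length `n_labels`.
#' @return An object of class `fixture_cnn`.
#' @export
build_fixture_cnn <- function(n_labels, seed, input_shape = c(32L, 32L, 1L),
                              channels = c(8L, 16L, 16L),
                              label_names = NULL) {
  stopifnot(n_labels >= 1L, length(channels) >= 2L, length(input_shape) == 3L)
  k <- 3L
  down <- 2L^(length(channels) - 1L)
  if (input_shape[1L] %% down != 0L || input_shape[2L] %% down != 0L) {
    stop("input height/width must be divisible by ", down)
  }
  set.seed(as.integer(seed))
  cin <- input_shape[3L]
  blocks <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    cout <- channels[i]
    blocks[[i]] <- list(
      W = matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                 k * k * cin, cout),
      b = numeric(cout),
      k = k,
      pool = i < length(channels)
    )
    cin <- cout
  }
  cf <- channels[length(channels)]
  head <- list(
    W = matrix(stats::rnorm(cf * n_labels, sd = sqrt(1 / cf)), cf, n_labels),
    b = numeric(n_labels)
  )
  if (!is.null(label_names)) stopifnot(length(label_names) == n_labels)
  structure(
    list(blocks = blocks, head = head, n_labels = n_labels,
         input_shape = as.integer(input_shape),
         channels = as.integer(channels),
         label_names = label_names, seed = as.integer(seed)),
    class = "fixture_cnn"
  )
}

#' @export
print.fixture_cnn <- function(x, ...) {
  cat(sprintf(
    "<fixture_cnn> input %s, conv channels %s, GAP dim %d, %d sigmoid outputs\n",
    paste(x$input_shape, collapse = "x"),
    paste(x$channels, collapse = "-"),
    x$channels[length(x$channels)], x$n_labels
  ))
  invisible(x)
}

# ---- forward / predict -----------------------------------------------------

# Full forward pass. keep_cache = TRUE stores everything backprop needs.
.cnn_forward <- function(model, x, keep_cache = FALSE) {
  x <- .as_batch(x)
  stopifnot(identical(dim(x)[1:3], as.integer(model$input_shape)))
  caches <- if (keep_cache) vector("list", length(model$blocks)) else NULL
  h <- x
  for (i in seq_along(model$blocks)) {
    bl <- model$blocks[[i]]
    cv <- .conv_forward(h, bl$W, bl$b, bl$k)
    a <- pmax(cv$y, 0)
    if (bl$pool) {
      mp <- .maxpool_forward(a)
      h <- mp$y
    } else {
      mp <- NULL
      h <- a
    }
    if (keep_cache) {
      caches[[i]] <- list(conv = cv, relu_mask = cv$y > 0, pool = mp)
    }
  }
  fmaps <- h # (Hf, Wf, Cf, N), post-ReLU final conv maps
  gap <- .gap_forward(fmaps) # (N, Cf)
  logits <- sweep(gap %*% model$head$W, 2L, model$head$b, `+`)
  probs <- stats::plogis(logits)
  if (!is.null(model$label_names)) colnames(probs) <- model$label_names
  list(probs = probs, logits = logits, fmaps = fmaps, gap = gap,
       caches = caches)
}

#' Predict label probabilities with a fixture CNN
#'
#' @param object A `fixture_cnn`.
#' @param images A single image (matrix or array), a list of images, or a
#'   batch array `(H, W, C, N)`.
#' @param ... Unused.
#' @return Matrix of probabilities, one row per image, one column per label.
#' @export
predict.fixture_cnn <- function(object, images, ...) {
  .cnn_forward(object, images)$probs
}

#' Final convolutional feature maps of a fixture CNN
#'
#' Returns the post-ReLU activations of the last convolutional block — the
#' maps that global average pooling collapses into the image embedding, and
#' the maps Grad-CAM weights.
#'
#' @inheritParams predict.fixture_cnn
#' @param model A `fixture_cnn`.
#' @return Array `(Hf, Wf, Cf, N)`.
#' @export
cnn_feature_maps <- function(model, images) {
  .cnn_forward(model, images)$fmaps
}

#' GAP embedding vectors of a fixture CNN
#'
#' @inheritParams cnn_feature_maps
#' @return Matrix `(N, Cf)`: the channel-wise spatial mean of the final
#'   convolutional feature maps.
#' @export
cnn_gap <- function(model, images) {
  .cnn_forward(model, images)$gap
}

#' Gradient of an output logit with respect to the final conv maps
#'
#' Backpropagates the pre-sigmoid logit of one output unit through the dense
#' head and the GAP layer down to the final convolutional feature maps. This
#' is the gradient field Grad-CAM spatially averages into channel weights.
#'
#' @param model A `fixture_cnn`.
#' @param image One image (matrix or `(H, W, C)` array).
#' @param class_index Output unit (1-based) whose logit is differentiated.
#' @return Array `(Hf, Wf, Cf)` of gradients.
#' @export
cnn_logit_gradient <- function(model, image, class_index) {
  stopifnot(class_index >= 1L, class_index <= model$n_labels)
  fw <- .cnn_forward(model, image)
  fd <- dim(fw$fmaps)
  dlogits <- matrix(0, nrow = fd[4L], ncol = model$n_labels)
  dlogits[, class_index] <- 1
  dgap <- dlogits %*% t(model$head$W)
  g <- .gap_backward(dgap, fd)
  array(g[, , , 1L], fd[1:3])
}

# ---- training --------------------------------------------------------------

.bce_loss <- function(probs, y) {
  eps <- 1e-12
  -mean(y * log(pmax(probs, eps)) + (1 - y) * log(pmax(1 - probs, eps)))
}

.adam_init <- function(par) list(m = par * 0, v = par * 0)

.adam_step <- function(par, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# One full backward pass; returns gradients mirroring the parameter layout.
.cnn_backward <- function(model, fw, y) {
  n <- nrow(fw$probs)
  dlogits <- (fw$probs - y) / (n * ncol(y))
  grads <- list(head = list(
    W = crossprod(fw$gap, dlogits),
    b = colSums(dlogits)
  ))
  dgap <- dlogits %*% t(model$head$W)
  dh <- .gap_backward(dgap, dim(fw$fmaps))
  gb <- vector("list", length(model$blocks))
  for (i in rev(seq_along(model$blocks))) {
    bl <- model$blocks[[i]]
    cache <- fw$caches[[i]]
    if (bl$pool) dh <- .maxpool_backward(dh, cache$pool)
    dh <- dh * cache$relu_mask
    cb <- .conv_backward(dh, cache$conv, bl$W, bl$k)
    gb[[i]] <- list(W = cb$dW, b = cb$db)
    dh <- cb$dx
  }
  grads$blocks <- gb
  grads
}

#' Train a fixture CNN with Adam on binary cross entropy
#'
#' Mini-batch training with an optional per-epoch learning-rate decay, early
#' stopping on validation mean AUC, and best-epoch checkpointing. With no
#' validation set the final-epoch weights are returned.
#'
#' @param model A `fixture_cnn`.
#' @param images Training images (list or batch array).
#' @param labels Binary matrix, one row per image, one column per label.
#' @param epochs Number of epochs.
#' @param lr Initial learning rate.
#' @param lr_decay Multiplicative factor applied to the learning rate after
#'   each epoch (1 = constant).
#' @param batch_size Mini-batch size.
#' @param val Optional list `list(images =, labels =)` used for validation
#'   mean AUC after each epoch.
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (`Inf` disables early stopping).
#' @param seed Seed for mini-batch shuffling.
#' @param verbose Print one line per epoch.
#' @return List with elements `model` (best weights if validated, else final),
#'   and `history` (data frame: epoch, lr, train_loss, val_auc).
#' @export
train_cnn <- function(model, images, labels, epochs = 5L, lr = 5e-3,
                      lr_decay = 1, batch_size = 32L, val = NULL,
                      patience = Inf, seed = 1L, verbose = FALSE) {
  x <- .as_batch(images)
  labels <- as.matrix(labels)
  n <- dim(x)[4L]
  stopifnot(nrow(labels) == n, ncol(labels) == model$n_labels, epochs >= 1L)
  set.seed(as.integer(seed))
  states <- list(
    head = list(W = .adam_init(model$head$W), b = .adam_init(model$head$b)),
    blocks = lapply(model$blocks, function(bl) {
      list(W = .adam_init(bl$W), b = .adam_init(bl$b))
    })
  )
  t_step <- 0L
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_auc = numeric())
  best <- list(auc = -Inf, model = model, epoch = 0L)
  stale <- 0L
  cur_lr <- lr
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric()
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- labels[idx, , drop = FALSE]
      fw <- .cnn_forward(model, xb, keep_cache = TRUE)
      losses <- c(losses, .bce_loss(fw$probs, yb))
      gr <- .cnn_backward(model, fw, yb)
      t_step <- t_step + 1L
      up <- .adam_step(model$head$W, gr$head$W, states$head$W, cur_lr, t_step)
      model$head$W <- up$par; states$head$W <- up$state
      up <- .adam_step(model$head$b, gr$head$b, states$head$b, cur_lr, t_step)
      model$head$b <- up$par; states$head$b <- up$state
      for (i in seq_along(model$blocks)) {
        up <- .adam_step(model$blocks[[i]]$W, gr$blocks[[i]]$W,
                         states$blocks[[i]]$W, cur_lr, t_step)
        model$blocks[[i]]$W <- up$par; states$blocks[[i]]$W <- up$state
        up <- .adam_step(model$blocks[[i]]$b, gr$blocks[[i]]$b,
                         states$blocks[[i]]$b, cur_lr, t_step)
        model$blocks[[i]]$b <- up$par; states$blocks[[i]]$b <- up$state
      }
    }
    val_auc <- NA_real_
    if (!is.null(val)) {
      vp <- .cnn_forward(model, val$images)$probs
      aucs <- vapply(seq_len(ncol(vp)), function(j) {
        yj <- val$labels[, j]
        if (length(unique(yj)) < 2L) return(NA_real_)
        roc_auc(vp[, j], yj)$auc
      }, numeric(1))
      val_auc <- mean(aucs, na.rm = TRUE)
      if (val_auc > best$auc + 1e-12) {
        best <- list(auc = val_auc, model = model, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = cur_lr,
                                   train_loss = mean(losses),
                                   val_auc = val_auc))
    if (verbose) {
      message(sprintf("epoch %d lr %.2g loss %.4f val_auc %s", ep, cur_lr,
                      mean(losses),
                      if (is.na(val_auc)) "-" else sprintf("%.3f", val_auc)))
    }
    if (!is.null(val) && stale >= patience) break
    cur_lr <- cur_lr * lr_decay
  }
  list(model = if (!is.null(val)) best$model else model, history = hist,
       best_epoch = if (!is.null(val)) best$epoch else epochs)
}
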