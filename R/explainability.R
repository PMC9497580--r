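# Grad-CAM saliency and localization agreement: channel weights are the
# spatial mean of the gradient of a class logit with respect to the final
# convolutional feature maps; the rectified weighted sum of the maps is
# bilinearly upsampled to image size and min-max normalized. Maps can be
# averaged across models and across populations of images, thresholded at a
# quantile into binary masks, boxed, and compared with expert masks by
# intersection-over-expert-area.

.minmax_normalize <- function(m) {
  rng <- range(m)
  if (rng[2L] - rng[1L] <= 0) {
    attr(m, "degenerate") <- TRUE
    return(m * 0)
  }
  out <- (m - rng[1L]) / (rng[2L] - rng[1L])
  attr(out, "degenerate") <- FALSE
  out
}

.upsample_bilinear <- function(m, height, width) {
  if (nrow(m) == height && ncol(m) == width) return(m)
  as.matrix(EBImage::resize(EBImage::Image(m), w = height, h = width,
                            filter = "bilinear"))
}

#' Grad-CAM saliency map for one image and class
#'
#' Computes the gradient of the class logit with respect to the final
#' convolutional feature maps, averages it spatially into per-channel
#' weights, forms the rectified (ReLU) weighted sum of the maps, upsamples
#' bilinearly to the input image size, and min-max normalizes to `[0, 1]`.
#' For a GAP-head network this reproduces the classical class activation
#' map up to normalization.
#'
#' If every channel contributes negatively the rectified map is identically
#' zero; it is returned as zeros with attribute `degenerate = TRUE`.
#'
#' @param model A `fixture_cnn`.
#' @param image One image (matrix, `(H, W, C)` array, or `processed_image`).
#' @param class_index Output unit (1-based) to explain; a label name is also
#'   accepted when the model carries label names.
#' @return A saliency matrix of the image's height/width in `[0, 1]`.
#' @export
grad_cam <- function(model, image, class_index) {
  if (is.character(class_index)) {
    stopifnot(!is.null(model$label_names))
    class_index <- match(class_index, model$label_names)
    if (is.na(class_index)) stop("unknown label name", call. = FALSE)
  }
  fw <- .cnn_forward(model, image)
  fmaps <- array(fw$fmaps[, , , 1L], dim(fw$fmaps)[1:3])
  grads <- cnn_logit_gradient(model, image, class_index)
  alpha <- apply(grads, 3L, mean)
  cam <- matrix(0, dim(fmaps)[1L], dim(fmaps)[2L])
  for (ch in seq_along(alpha)) cam <- cam + alpha[ch] * fmaps[, , ch]
  cam <- pmax(cam, 0)
  img_dim <- dim(.as_batch(image))[1:2]
  cam <- .upsample_bilinear(cam, img_dim[1L], img_dim[2L])
  if (max(cam) <= 0) {
    warning("Grad-CAM map is identically zero after rectification")
    out <- cam * 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  .minmax_normalize(cam)
}

#' Average saliency maps
#'
#' Each map is min-max normalized first (different models produce gradients
#' on incomparable scales), then the pixelwise mean is taken and
#' renormalized. Used both model-level (maps of several models for one
#' image) and population-level (maps of many images for one model/class).
#'
#' @param maps List of equally sized saliency matrices.
#' @return Averaged, renormalized saliency matrix; attribute `degenerate` is
#'   `TRUE` if the mean map was constant.
#' @export
average_maps <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1L)
  d <- dim(maps[[1L]])
  acc <- matrix(0, d[1L], d[2L])
  for (m in maps) {
    if (!identical(dim(m), d)) stop("saliency maps differ in shape",
                                    call. = FALSE)
    acc <- acc + .minmax_normalize(m)
  }
  .minmax_normalize(acc / length(maps))
}

#' Threshold a saliency map at a quantile
#'
#' The mask is `TRUE` where the map strictly exceeds the empirical
#' `q`-quantile of its own pixel values; for a map of distinct values this
#' leaves very nearly a `1 - q` fraction of pixels. A constant map yields an
#' empty mask with a warning.
#'
#' @param map Saliency matrix.
#' @param q Quantile in `(0, 1)`.
#' @return Logical matrix of the same shape.
#' @export
quantile_mask <- function(map, q = 0.8) {
  .assert_scalar_in(q, 0, 1, "q", open_lo = TRUE, open_hi = TRUE)
  if (diff(range(map)) == 0) {
    warning("constant saliency map: empty mask")
    return(matrix(FALSE, nrow(map), ncol(map)))
  }
  thr <- stats::quantile(map, q, names = FALSE, type = 7)
  map > thr
}

# 8-connected component labeling by breadth-first flood fill.
.label_components <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  offs <- cbind(rep(-1:1, 3L), rep(-1:1, each = 3L))
  offs <- offs[!(offs[, 1L] == 0L & offs[, 2L] == 0L), ]
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      px <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (px - 1L) %% h + 1L
      cc <- (px - 1L) %/% h + 1L
      nr <- r + offs[, 1L]
      nc <- cc + offs[, 2L]
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nb <- (nc[ok] - 1L) * h + nr[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Bounding box(es) of a binary mask
#'
#' Union mode returns the tightest axis-aligned box covering all `TRUE`
#' pixels; component mode returns one box per 8-connected component. An
#' empty mask yields zero boxes (an empty data frame), not an error.
#'
#' @param mask Logical matrix.
#' @param mode `"union"` or `"components"`.
#' @return Data frame with columns `row_min`, `row_max`, `col_min`,
#'   `col_max` (1-based, inclusive), one row per box.
#' @export
bounding_box <- function(mask, mode = c("union", "components")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mask), is.logical(mask))
  empty <- data.frame(row_min = integer(), row_max = integer(),
                      col_min = integer(), col_max = integer())
  if (!any(mask)) return(empty)
  if (mode == "union") {
    idx <- which(mask, arr.ind = TRUE)
    return(data.frame(row_min = min(idx[, 1L]), row_max = max(idx[, 1L]),
                      col_min = min(idx[, 2L]), col_max = max(idx[, 2L])))
  }
  lab <- .label_components(mask)
  do.call(rbind, lapply(seq_len(max(lab)), function(g) {
    idx <- which(lab == g, arr.ind = TRUE)
    data.frame(row_min = min(idx[, 1L]), row_max = max(idx[, 1L]),
               col_min = min(idx[, 2L]), col_max = max(idx[, 2L]))
  }))
}

# Rasterize boxes back into a mask (for the box-based agreement variant).
.boxes_to_mask <- function(boxes, height, width) {
  m <- matrix(FALSE, height, width)
  for (i in seq_len(nrow(boxes))) {
    m[boxes$row_min[i]:boxes$row_max[i],
      boxes$col_min[i]:boxes$col_max[i]] <- TRUE
  }
  m
}

#' Localization agreement with an expert mask
#'
#' Intersection area over the total area identified by the expert:
#' `|pred & expert| / |expert|`. Monotone in the predicted mask — adding
#' predicted pixels never decreases it. With `on = "box"` the predicted
#' mask is first replaced by its union bounding box.
#'
#' @param pred_mask Predicted logical matrix (e.g. a [quantile_mask()]).
#' @param expert_mask Expert logical matrix of the same shape.
#' @param on `"mask"` (default) or `"box"`.
#' @return Scalar in `[0, 1]`; `NA` with a warning if the expert mask is
#'   empty.
#' @export
agreement <- function(pred_mask, expert_mask, on = c("mask", "box")) {
  on <- match.arg(on)
  stopifnot(is.matrix(pred_mask), is.matrix(expert_mask),
            identical(dim(pred_mask), dim(expert_mask)))
  if (!any(expert_mask)) {
    warning("empty expert mask: agreement undefined")
    return(NA_real_)
  }
  if (on == "box") {
    bb <- bounding_box(pred_mask, "union")
    pred_mask <- .boxes_to_mask(bb, nrow(pred_mask), ncol(pred_mask))
  }
  sum(pred_mask & expert_mask) / sum(expert_mask)
}
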