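# Image preparation: quantile clipping of saturated landmark pixels, unit
# scaling, optional center crop, bilinear resize with 3-channel replication,
# and per-channel standardization. The canonical chain is
# clip -> scale -> resize/stack -> standardize.

#' Per-channel ImageNet normalization constants
#' @format Named list with `means` and `sds`, each length 3.
#' @export
imagenet_norm <- list(means = c(0.485, 0.456, 0.406),
                      sds = c(0.229, 0.224, 0.225))

#' Clip image intensities at an upper quantile
#'
#' Caps every pixel at the empirical `q`-quantile of the image's own values
#' (linear interpolation between order statistics). With the default
#' `q = 0.9995`, rare saturated landmark clusters are pulled down to
#' background level while all other pixels pass through unchanged.
#'
#' @param img Numeric matrix of finite nonnegative intensities.
#' @param q Quantile threshold in `(0, 1]`.
#' @return Matrix of the same shape with `max(out) <=` the `q`-quantile.
#' @export
clip_quantile <- function(img, q = 0.9995) {
  .assert_scalar_in(q, 0, 1, "q", open_lo = TRUE)
  stopifnot(is.matrix(img), all(is.finite(img)))
  thr <- stats::quantile(img, q, names = FALSE, type = 7)
  pmin(img, thr)
}

#' Scale an image to the unit interval
#'
#' Affine map sending the minimum to 0 and the maximum to 1. A constant
#' image has no range to scale; it is returned as all zeros with a warning.
#'
#' @param img Numeric matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
scale_unit <- function(img) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  rng <- range(img)
  if (rng[1L] == rng[2L]) {
    warning("constant image: unit scaling returns all zeros")
    return(img * 0)
  }
  (img - rng[1L]) / (rng[2L] - rng[1L])
}

#' Resize an image and replicate it over three channels
#'
#' Optionally extracts a centered crop (a stand-in for anatomical region
#' extraction), bilinearly resizes to `side x side`, and stacks the result
#' as three identical channels, ready for networks expecting RGB input.
#'
#' @param img Numeric matrix.
#' @param side Output side in pixels.
#' @param crop Optional center-crop fraction in `(0, 1]`; `NULL` for none.
#' @return A `processed_image`: array `(side, side, 3)` with identical
#'   channels and attributes `channel_means`/`channel_sds` (unset until
#'   [standardize()] runs).
#' @export
resize_and_stack <- function(img, side = 224L, crop = NULL) {
  stopifnot(is.matrix(img), all(is.finite(img)), side >= 2L)
  if (!is.null(crop)) {
    .assert_scalar_in(crop, 0, 1, "crop", open_lo = TRUE)
    h <- nrow(img); w <- ncol(img)
    ch <- max(2L, round(h * crop)); cw <- max(2L, round(w * crop))
    r0 <- floor((h - ch) / 2); c0 <- floor((w - cw) / 2)
    img <- img[r0 + seq_len(ch), c0 + seq_len(cw), drop = FALSE]
  }
  resized <- if (nrow(img) == side && ncol(img) == side) {
    img
  } else {
    as.matrix(EBImage::resize(EBImage::Image(img), w = side, h = side,
                              filter = "bilinear"))
  }
  out <- array(resized, c(side, side, 3L))
  structure(out, class = "processed_image",
            channel_means = NULL, channel_sds = NULL)
}

#' Standardize a processed image per channel
#'
#' Subtracts per-channel means and divides by per-channel standard
#' deviations; the constants used are recorded on the result.
#'
#' @param img A `processed_image` (array `(H, W, 3)`).
#' @param means,sds Per-channel constants (length 3 or scalars); defaults are
#'   the ImageNet statistics in [imagenet_norm].
#' @return Standardized `processed_image` with `channel_means`/`channel_sds`
#'   attributes set.
#' @export
standardize <- function(img, means = imagenet_norm$means,
                        sds = imagenet_norm$sds) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3L] == 3L)
  means <- rep_len(means, 3L)
  sds <- rep_len(sds, 3L)
  if (any(sds <= 0)) stop("`sds` must be positive", call. = FALSE)
  out <- unclass(img)
  for (ch in 1:3) out[, , ch] <- (out[, , ch] - means[ch]) / sds[ch]
  structure(out, class = "processed_image",
            channel_means = means, channel_sds = sds)
}

#' Run the full preprocessing chain on one image
#'
#' `clip_quantile` then `scale_unit` then `resize_and_stack` then
#' `standardize`, in that fixed order.
#'
#' @inheritParams clip_quantile
#' @inheritParams resize_and_stack
#' @inheritParams standardize
#' @return A standardized `processed_image`.
#' @export
preprocess_image <- function(img, q = 0.9995, side = 224L, crop = NULL,
                             means = imagenet_norm$means,
                             sds = imagenet_norm$sds) {
  standardize(resize_and_stack(scale_unit(clip_quantile(img, q)),
                               side = side, crop = crop),
              means = means, sds = sds)
}

# ---- image I/O -------------------------------------------------------------

#' Write a grayscale image as 16-bit PNG
#'
#' Intensities are affinely mapped from `[0, max]` to the 16-bit range.
#'
#' @param img Nonnegative intensity matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0))
  mx <- max(img, 1e-12)
  png::writePNG(img / mx, path)
  invisible(path)
}

#' Read a grayscale PNG or TIFF as an intensity matrix
#'
#' Multi-channel files are averaged to one channel.
#'
#' @param path PNG or TIFF file.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  im <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    as.array(EBImage::readImage(path))
  } else {
    png::readPNG(path)
  }
  if (length(dim(im)) == 3L) im <- apply(im, c(1L, 2L), mean)
  as.matrix(im)
}
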