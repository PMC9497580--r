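# Independent oracle implementations used to cross-check package code.
# These deliberately use different algorithms from the implementation.

# Exhaustive pairwise concordance AUC, ties counted one half.
oracle_pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# Direct element-by-element coding of the two ensemble combination rules.
oracle_binary_entropy <- function(p) {
  if (p == 0 || p == 1) return(0)
  -p * log(p, base = 2) - (1 - p) * log(1 - p, base = 2)
}

oracle_simple_average <- function(P) {
  out <- numeric(ncol(P))
  for (i in seq_len(ncol(P))) {
    s <- 0
    for (k in seq_len(nrow(P))) s <- s + P[k, i]
    out[i] <- s / nrow(P)
  }
  out
}

oracle_entropy_average <- function(P) {
  out <- numeric(ncol(P))
  for (i in seq_len(ncol(P))) {
    s <- 0
    for (k in seq_len(nrow(P))) {
      s <- s + (1 - oracle_binary_entropy(P[k, i])) * P[k, i]
    }
    out[i] <- s
  }
  out
}

# Class activation map for a GAP-head network, built straight from the dense
# weights (no gradients involved): relu(sum_c w_c A_c), upsampled, min-max
# normalized.
oracle_cam <- function(model, image, class_index) {
  fmaps <- cnn_feature_maps(model, image)
  fmaps <- array(fmaps[, , , 1], dim(fmaps)[1:3])
  w <- model$head$W[, class_index]
  m <- matrix(0, dim(fmaps)[1], dim(fmaps)[2])
  for (ch in seq_along(w)) m <- m + w[ch] * fmaps[, , ch]
  m <- pmax(m, 0)
  d <- dim(cxrtransfer:::.as_batch(image))[1:2]
  if (!identical(dim(m), d)) {
    m <- as.matrix(EBImage::resize(EBImage::Image(m), w = d[1], h = d[2],
                                   filter = "bilinear"))
  }
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

# Connected components by dilation-to-fixpoint growth (8-neighborhood).
oracle_components <- function(mask) {
  dilate8 <- function(m) {
    h <- nrow(m); w <- ncol(m)
    out <- m
    for (dr in -1:1) {
      for (dc in -1:1) {
        src_r <- max(1, 1 - dr):min(h, h - dr)
        src_c <- max(1, 1 - dc):min(w, w - dc)
        out[src_r + dr, src_c + dc] <- out[src_r + dr, src_c + dc] |
          m[src_r, src_c]
      }
    }
    out
  }
  remaining <- mask
  comps <- list()
  while (any(remaining)) {
    seed <- matrix(FALSE, nrow(mask), ncol(mask))
    seed[which(remaining)[1]] <- TRUE
    repeat {
      grown <- dilate8(seed) & mask
      if (identical(grown, seed)) break
      seed <- grown
    }
    comps[[length(comps) + 1]] <- seed
    remaining <- remaining & !seed
  }
  comps
}
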