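# ROC curves and AUROC, the framework's sole performance metric. AUC is
# computed by the midrank (Mann-Whitney) formula so tied scores count 1/2,
# making the estimator identical to exhaustive pairwise concordance.

#' ROC curve and AUC for one label
#'
#' AUC equals the probability that a random positive is scored above a
#' random negative, with ties counted one half (midrank convention); the
#' trapezoidal area under the tie-grouped ROC curve gives the same number.
#'
#' @param scores Numeric vector of scores (higher = more positive).
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return List with `auc`, `roc` (data frame of `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1)), `n_pos`, `n_neg`. If only one class is
#'   present, `auc` is `NA` with a warning.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUC undefined: only one class present")
    return(list(auc = NA_real_, roc = NULL, n_pos = n_pos, n_neg = n_neg))
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # tie-grouped ROC points, thresholds descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1L - y)[grp_end]
  roc <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  list(auc = auc, roc = roc, n_pos = n_pos, n_neg = n_neg)
}

#' Per-label AUCs for a score matrix
#'
#' @param scores `n x L` matrix of scores.
#' @param labels `n x L` binary matrix.
#' @return A `roc_result`: list with `per_label` (named list of [roc_auc()]
#'   results), `auc` (named vector), and `mean_auc` (unweighted mean over
#'   labels with a defined AUC).
#' @export
evaluate_predictions <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.matrix(labels)
  stopifnot(identical(dim(scores), dim(labels)))
  nms <- colnames(labels)
  if (is.null(nms)) nms <- paste0("label", seq_len(ncol(labels)))
  per <- lapply(seq_len(ncol(scores)), function(j) {
    withCallingHandlers(
      roc_auc(scores[, j], labels[, j]),
      warning = function(w) invokeRestart("muffleWarning")
    )
  })
  names(per) <- nms
  aucs <- vapply(per, `[[`, numeric(1), "auc")
  structure(list(per_label = per, auc = aucs, mean_auc = mean_auc(aucs)),
            class = "roc_result")
}

#' Unweighted mean AUC over labels
#'
#' Labels whose AUC is undefined (single-class) are excluded.
#'
#' @param aucs Named numeric vector of per-label AUCs (may contain `NA`), or
#'   a `roc_result`.
#' @return Scalar mean AUC.
#' @export
mean_auc <- function(aucs) {
  if (inherits(aucs, "roc_result")) aucs <- aucs$auc
  if (all(is.na(aucs))) return(NA_real_)
  mean(aucs, na.rm = TRUE)
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result>\n")
  print(round(x$auc, 3))
  cat(sprintf("mean AUC: %.3f\n", x$mean_auc))
  invisible(x)
}
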