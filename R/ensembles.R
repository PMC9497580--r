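# Ensemble combination of per-classifier probabilities: simple averaging and
# entropy-weighted averaging, where each classifier's vote on a label is
# weighted by its confidence 1 - H(p) (H = base-2 binary entropy). The
# entropy-weighted combination is provided both literally (weights need not
# sum to one, so scores can exceed 1 — harmless for AUC, which only ranks)
# and in a normalized variant.

#' Binary entropy in base 2
#'
#' `H(p) = -p log2(p) - (1 - p) log2(1 - p)`, with the convention
#' `0 * log(0) = 0` so that `H(0) = H(1) = 0`.
#'
#' @param p Probabilities in `[0, 1]` (vectorized).
#' @return Entropies in `[0, 1]`.
#' @export
binary_entropy <- function(p) {
  .assert_prob(p)
  h <- numeric(length(p))
  in01 <- p > 0 & p < 1
  pi <- p[in01]
  h[in01] <- -pi * log2(pi) - (1 - pi) * log2(1 - pi)
  h
}

.check_pred_matrix <- function(P) {
  P <- as.matrix(P)
  if (length(P) == 0L) stop("empty prediction matrix", call. = FALSE)
  .assert_prob(P, "prediction matrix")
  P
}

.ensemble_result <- function(scores, method, K) {
  structure(list(scores = scores, method = method, n_classifiers = K),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble_prediction> method %s over %d classifiers\n",
              x$method, x$n_classifiers))
  print(x$scores)
  invisible(x)
}

#' Simple-average ensemble
#'
#' Per label, the arithmetic mean of the K classifiers' probabilities.
#'
#' @param P Prediction matrix, K classifiers x L labels, entries in `[0, 1]`.
#' @return An `ensemble_prediction` with per-label scores in `[0, 1]`.
#' @export
simple_average <- function(P) {
  P <- .check_pred_matrix(P)
  .ensemble_result(colMeans(P), "simple", nrow(P))
}

#' Entropy-weighted-average ensemble
#'
#' Per label, `sum_k (1 - H(p_k)) * p_k`: each classifier's probability is
#' weighted by its confidence, so a maximally uncertain classifier
#' (`p = 0.5`) contributes exactly nothing. In literal form the weights do
#' not sum to one and scores live in `[0, K]`; with `normalize = TRUE` the
#' sum is divided by the total weight (falling back to the simple average
#' for a label whose total weight is zero).
#'
#' @inheritParams simple_average
#' @param normalize Divide by the summed weights per label.
#' @return An `ensemble_prediction`.
#' @export
entropy_weighted_average <- function(P, normalize = FALSE) {
  P <- .check_pred_matrix(P)
  W <- 1 - matrix(binary_entropy(P), nrow(P), ncol(P))
  num <- colSums(W * P)
  if (!normalize) {
    return(.ensemble_result(num, "entropy", nrow(P)))
  }
  den <- colSums(W)
  scores <- ifelse(den > 0, num / den, colMeans(P))
  .ensemble_result(scores, "entropy_normalized", nrow(P))
}

#' Apply an ensemble method across samples
#'
#' @param preds Array `(K, L, n)` of per-sample prediction matrices.
#' @param method `"simple"`, `"entropy"` or `"entropy_normalized"`.
#' @return `n x L` matrix of ensemble scores.
#' @export
ensemble_scores <- function(preds, method = c("simple", "entropy",
                                              "entropy_normalized")) {
  method <- match.arg(method)
  stopifnot(length(dim(preds)) == 3L)
  n <- dim(preds)[3L]
  L <- dim(preds)[2L]
  res <- vapply(seq_len(n), function(i) {
    P <- preds[, , i, drop = FALSE]
    dim(P) <- dim(preds)[1:2]
    switch(method,
      simple = simple_average(P),
      entropy = entropy_weighted_average(P, normalize = FALSE),
      entropy_normalized = entropy_weighted_average(P, normalize = TRUE)
    )$scores
  }, numeric(L))
  out <- if (L == 1L) matrix(res, ncol = 1L) else t(res)
  colnames(out) <- dimnames(preds)[[2L]]
  out
}
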