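#' @keywords internal
"_PACKAGE"

# Fixed per-purpose offsets so one experiment seed fans out to independent
# child streams; partial reruns of a stage reuse the same child seed.
.seed_offsets <- c(
  images = 11L, predictions = 23L, embeddings = 37L, cnn = 53L,
  split = 71L, trees = 89L, stacking = 107L, finetune = 131L,
  explain = 151L
)

#' Derive a child seed from an experiment seed
#'
#' One global seed fans out to per-stage seeds by fixed offsets, so that
#' rerunning a single stage reproduces exactly what a full run would have
#' done. The result always fits in a 32-bit integer.
#'
#' @param seed Integer master seed.
#' @param purpose One of `r paste0('"', names(.seed_offsets), '"', collapse = ", ")`.
#' @param index Optional extra index (e.g. replicate or model number).
#' @return An integer seed.
#' @export
child_seed <- function(seed, purpose, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  off <- .seed_offsets[[match.arg(purpose, names(.seed_offsets))]]
  as.integer((abs(seed) + 1009 * off + 9973 * index) %% .Machine$integer.max)
}

.assert_prob <- function(p, what = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(sprintf("`%s` must be numeric in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}

.assert_scalar_in <- function(x, lo, hi, what, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) stop(sprintf("`%s` must be a scalar in %s%g, %g%s", what,
                        if (open_lo) "(" else "[", lo, hi,
                        if (open_hi) ")" else "]"), call. = FALSE)
  invisible(x)
}
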