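# Shared fixtures. The trained blob-task network is expensive (~30 s), so it
# is built lazily once per test run and reused by the CNN, explainability and
# acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

# A disc in a fixed quadrant, 400 images, 80/20 split; network trained for
# five epochs on the training split.
blob_fixture <- function() {
  if (!exists("fix", envir = .fixture_cache)) {
    spec <- blob_task_spec(n_images = 400, side = 32, seed = 7)
    dat <- generate_images(spec)
    x <- lapply(dat$images, preprocess_image, side = 32,
                means = 0.5, sds = 0.5)
    split <- stratified_split(dat$labels, c(0.8, 0.2), seed = 11)
    net <- build_fixture_cnn(1, seed = 11, input_shape = c(32, 32, 3))
    tr <- train_cnn(net, x[split$train],
                    dat$labels[split$train, , drop = FALSE],
                    epochs = 5, lr = 5e-3, seed = 1)
    assign("fix", list(spec = spec, dat = dat, x = x, split = split,
                       model = tr$model, history = tr$history),
           envir = .fixture_cache)
  }
  get("fix", envir = .fixture_cache)
}

# Tiny untrained network for fast structural tests.
tiny_net <- function(n_labels = 2, seed = 5, side = 16,
                     channels = c(4, 6)) {
  build_fixture_cnn(n_labels, seed = seed,
                    input_shape = c(side, side, 1), channels = channels)
}

random_image <- function(side = 16, seed = 1) {
  set.seed(seed)
  matrix(abs(rnorm(side * side)), side, side)
}
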