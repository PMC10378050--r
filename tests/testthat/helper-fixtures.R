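# Shared fixtures: random unit-norm double-view batches and a cached
# synthetic image dataset (generated once per test run).

`%||%` <- function(a, b) if (is.null(a)) b else a

# random double-view batch: N sources, dimension d, labels drawn from
# n_classes (both views of a source share the label)
random_batch <- function(n, d, n_classes = 3L, seed = 1L) {
  set.seed(seed)
  z <- normalize_rows(matrix(rnorm(2 * n * d), 2 * n))
  lab <- sample(0:(n_classes - 1L), n, replace = TRUE)
  list(z = z, pairing = view_pairing(2L * n), labels = as.integer(c(lab, lab)))
}

# batch of identical unit rows (the analytic spot-value case)
identical_batch <- function(n_views = 4L, d = 3L) {
  z <- matrix(0, n_views, d)
  z[, 1] <- 1
  list(z = z, pairing = view_pairing(n_views),
       labels = integer(n_views))
}

# small synthetic image dataset, generated once and reused across tests
synth_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "amcontrast_synth100")
      cache <<- generate_dataset(
        synthetic_image_config(size = 32L, seed = 11L),
        counts = c(20L, 20L, 20L, 20L, 20L), dir = dir)
    }
    cache
  }
})

# tiny architecture for 32px fixtures
tiny_spec <- function(n_classes = 5L) {
  model_spec(image_size = 32L, channels = c(8L, 16L, 32L), proj_hidden = 32L,
             d_p = 16L, n_classes = n_classes)
}

tiny_control <- function(...) {
  args <- list(...)
  defaults <- list(epochs = 2L, batch_size = 8L, lr = 2e-3, task = "multiclass",
                   image_size = 32L, seed = 1L,
                   margin = margin_config(0.2, 0.1, 0.1, 1))
  do.call(train_config, utils::modifyList(defaults, args))
}
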