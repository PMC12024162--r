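# The bundled synthetic benchmark: 400 training and 100 held-out images
# at 64x64, 30 epochs, fixed seeds.  Trained once per test session and
# cached, because several acceptance properties are measured on the same
# pair of runs (with and without the sparse loss).

.bench_env <- new.env(parent = emptyenv())

benchmark_data <- function() {
  if (is.null(.bench_env$data))
    .bench_env$data <- list(train = lem_simulate(400, seed = 101),
                            test = lem_simulate(100, seed = 202))
  .bench_env$data
}

benchmark_fit <- function(sparse = TRUE) {
  key <- if (sparse) "fit_sparse" else "fit_plain"
  if (is.null(.bench_env[[key]])) {
    d <- benchmark_data()
    .bench_env[[key]] <- lem(d$train,
                             lem_benchmark_config(seed = 1,
                                                  use_sparse_loss = sparse))
  }
  .bench_env[[key]]
}

# Fraction of importance mass falling inside the dilated truth mask,
# for one test image.
mass_in_mask <- function(fit, image, dilate_px = 8) {
  loc <- localize(fit, image)
  if (sum(loc$map) == 0) return(NA_real_)
  dil <- lemap:::.dilate(image$mask, dilate_px)
  sum(loc$map * dil) / sum(loc$map)
}

# A small seeded backbone plus image for propagation tests.
tiny_net <- function(seed = 1, size = 16L, channels = c(3L, 4L)) {
  set.seed(seed)
  net <- lem_backbone(size, channels)
  img <- matrix(runif(size * size), size, size)
  list(net = net, img = img)
}
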