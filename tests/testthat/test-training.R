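# The training loop: schedules, determinism, degeneration to plain GAP
# training at alpha = 0, and learning progress.

test_that("training is bit-reproducible under a fixed seed", {
  ds <- lem_simulate(8, seed = 31)
  cfg <- lem_benchmark_config(seed = 5, max_epochs = 2, batch_size = 4)
  f1 <- lem(ds, cfg)
  f2 <- lem(ds, cfg)
  expect_identical(f1$net, f2$net)
  expect_identical(f1$history, f2$history)
  f3 <- lem(ds, lem_benchmark_config(seed = 6, max_epochs = 2,
                                     batch_size = 4))
  expect_false(identical(f1$net$proj$V, f3$net$proj$V))
})

test_that("single-class datasets are refused", {
  ds <- lem_simulate(6, class_balance = 1, seed = 32)
  expect_error(lem(ds), "single class")
  expect_error(lem(list()), "empty")
})

test_that("history records the exact schedules", {
  ds <- lem_simulate(8, seed = 33)
  cfg <- lem_config(lr = 1e-2, lr_decay = 0.5, lr_decay_every = 2,
                    alpha_start = 0.2, alpha_end = 0.8, alpha_ramp = 4,
                    max_epochs = 6, batch_size = 8, seed = 1)
  fit <- lem(ds, cfg)
  expect_equal(fit$history$lr, 1e-2 * 0.5^(floor(0:5 / 2)))
  expect_equal(fit$history$alpha,
               0.2 + 0.6 * pmin(1, (0:5) / 4))
  expect_equal(nrow(fit$history), 6)
})

test_that("training at alpha = 0 reproduces a plain GAP loop exactly", {
  ds <- lem_simulate(24, seed = 34)
  cfg <- lem_config(alpha_start = 0, alpha_end = 0, lr = 0.1, momentum = 0,
                    lam = 0, max_epochs = 3, batch_size = 8, seed = 2)
  fit <- lem(ds, cfg)
  # independent plain-GAP reference loop: cross-entropy on the sigmoid
  # of the mean score, vanilla SGD, identical seeding and shuffling
  labels <- lem_labels(ds)
  ref_hist <- numeric(3)
  net <- NULL
  lemap:::.with_seed(2L, {
    net <- lem_backbone(64)
    for (epoch in 0:2) {
      ord <- sample.int(24)
      tot <- 0
      for (start in seq(1, 24, by = 8)) {
        idx <- ord[start:(start + 7)]
        x <- lemap:::.dataset_array(ds$images[idx])
        fw <- lemap:::.net_forward(net, x)
        y <- lemap:::sigmoid(apply(fw$S, 3, mean))
        t <- labels[idx]
        tot <- tot + sum(classification_loss(y, t)) / 24
        hw <- prod(dim(fw$S)[1:2])
        dS <- array(rep((y - t) / hw, each = hw) / 8, dim = dim(fw$S))
        gr <- lemap:::.net_backward(net, fw, dS)
        net <- lemap:::.net_update(net, gr, 0.1)
      }
      ref_hist[epoch + 1] <- tot
    }
  })
  expect_identical(fit$history$l_gap, ref_hist)
  expect_identical(fit$net$proj$V, net$proj$V)
  expect_identical(fit$net$blocks[[1]]$W, net$blocks[[1]]$W)
})

test_that("the comparable-objective loss decreases over training", {
  # fixed alpha (so the objective is the same function at every epoch)
  # and mu = 0 (the penalty term legitimately grows as logits grow, so
  # only the classification part of the objective is monotone progress)
  ds <- lem_simulate(48, seed = 35)
  fit <- lem(ds, lem_benchmark_config(seed = 1, max_epochs = 11, mu = 0,
                                      alpha_start = 0.5, alpha_end = 0.5,
                                      alpha_ramp = 1))
  expect_lt(fit$history$total_j[11], fit$history$total_j[1])
})

test_that("the LEM and GAP probability paths agree on most held-out
           labels of the trained benchmark", {
  d <- benchmark_data()
  fit <- benchmark_fit(sparse = TRUE)
  y <- predict(fit, d$test)
  yg <- predict(fit, d$test, mode = "gap")
  # frozen from the measured benchmark: 0.85 agreement on the fixed
  # seed; the bound leaves room for seed-level variation only
  expect_gte(mean((y > 0.5) == (yg > 0.5)), 0.8)
})

test_that("predict returns consistent probability paths and artifacts", {
  ds <- lem_simulate(10, seed = 36)
  fit <- lem(ds, lem_benchmark_config(seed = 1, max_epochs = 2,
                                      batch_size = 5))
  p_gap <- predict(fit, ds, mode = "gap")
  full <- predict(fit, ds, type = "full")
  for (i in seq_along(full)) {
    M <- full[[i]]$score_map
    expect_equal(p_gap[i], 1 / (1 + exp(-mean(M))), tolerance = 1e-12)
    expect_equal(full[[i]]$y_lem,
                 aggregate_extrema(M)$y_lem, tolerance = 1e-12)
  }
  cl <- predict(fit, ds, type = "class")
  expect_identical(cl, as.integer(predict(fit, ds) > 0.5))
  # a constant score map yields the indifferent LEM probability
  net0 <- fit$net; net0$proj$V[] <- 0; net0$proj$b <- 0
  fit0 <- fit; fit0$net <- net0
  expect_equal(unique(predict(fit0, ds)), 0.5)
})

test_that("momentum accelerates but preserves determinism", {
  ds <- lem_simulate(16, seed = 37)
  cfg <- lem_benchmark_config(seed = 3, max_epochs = 2, batch_size = 8,
                              momentum = 0.9)
  f1 <- lem(ds, cfg)
  f2 <- lem(ds, cfg)
  expect_identical(f1$net, f2$net)
  f0 <- lem(ds, lem_benchmark_config(seed = 3, max_epochs = 2,
                                     batch_size = 8, momentum = 0))
  expect_false(identical(f0$net$proj$V, f1$net$proj$V))
})

test_that("the fit object supports the standard modelling methods", {
  ds <- lem_simulate(8, seed = 38)
  fit <- lem(ds, lem_benchmark_config(seed = 1, max_epochs = 2,
                                      batch_size = 8))
  expect_output(print(fit), "LEM fit: 8 training images")
  expect_output(print(summary(fit)), "loss history")
  cf <- coef(fit)
  expect_length(cf$blocks, 3)
  expect_length(cf$projection$V, 32)
  pdf(NULL)
  expect_invisible(plot(fit))
  loc <- localize(fit, ds$images[[1]])
  expect_output(print(loc), "LEM localization")
  expect_invisible(plot(loc))
  dev.off()
  expect_output(print(fit$config), "free factor")
  expect_output(print(ds), "8 images")
  # checkpoint survives a save/load round trip bit-exactly
  f <- tempfile(fileext = ".rds")
  lem_save(fit, f)
  back <- lem_load(f)
  expect_identical(back$net, fit$net)
  junk <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(lem_load(junk), "not a lemap checkpoint")
})
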