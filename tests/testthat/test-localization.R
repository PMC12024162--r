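# Extremum selection, top-down importance propagation, and mask scoring.

test_that("selection follows the decision branch and filters by sign", {
  S <- matrix(0, 4, 4); S[2, 2] <- 3; S[3, 4] <- -2
  E <- detect_extrema(S)
  ag <- aggregate_extrema(S, E)   # a_m = 3, a_b = -2: slightly malignant
  expect_gt(ag$y_lem, 0.5)
  sel <- select_extrema(S, E, ag)
  expect_identical(attr(sel, "status"), "ok")
  expect_true(all(sel$kind == "max"))
  expect_equal(nrow(sel), 1)      # only the positive maximum qualifies
  expect_equal(c(sel$row, sel$col), c(2, 2))
  # benign branch: minima with negative scores
  sel2 <- select_extrema(-S, detect_extrema(-S))
  expect_true(all(sel2$kind == "min"))
  expect_equal(nrow(sel2), 1)
})

test_that("a constant zero map yields an empty benign selection", {
  S <- matrix(0, 4, 4)
  sel <- select_extrema(S)   # y_lem = 0.5, benign branch, no negatives
  expect_equal(nrow(sel), 0)
  expect_identical(attr(sel, "status"), "empty")
  set.seed(71)
  net <- lem_backbone(16, c(2L, 2L))
  net$proj$V[] <- 0; net$proj$b <- 0   # forces an all-zero score map
  loc <- localize(net, matrix(runif(256), 16, 16))
  expect_identical(loc$status, "empty")
  expect_equal(sum(loc$map), 0)
  expect_equal(loc$n_extrema_used, 0L)
})

test_that("propagation matches the exhaustive per-neuron oracle", {
  for (seed in 1:5) {
    tn <- tiny_net(seed, size = 8L, channels = c(2L, 3L))
    fw <- lemap:::.net_forward(tn$net, lemap:::.as_image_array(tn$img))
    starts <- data.frame(row = c(1, 2), col = c(1, 2),
                         kind = c("max", "min"))
    ours <- lemap:::.propagate(tn$net, fw, starts)
    ref <- brute_propagate(tn$net, tn$img, starts)
    expect_equal(ours$map, ref, tolerance = 1e-10)
  }
})

test_that("each propagated extremum delivers unit mass when normalizers
           are positive, and the map is nonnegative", {
  for (seed in 6:10) {
    tn <- tiny_net(seed, size = 16L, channels = c(3L, 4L))
    fw <- lemap:::.net_forward(tn$net, lemap:::.as_image_array(tn$img))
    S <- fw$S[, , 1]
    E <- detect_extrema(S)
    ag <- aggregate_extrema(S, E)
    sel <- select_extrema(S, E, ag)
    if (nrow(sel) == 0) next
    pr <- lemap:::.propagate(tn$net, fw, sel)
    expect_true(all(pr$map >= 0))
    expect_equal(pr$delivered, nrow(sel), tolerance = 1e-5)
  }
})

test_that("single-extremum propagation via the public interface", {
  tn <- tiny_net(11, size = 16L, channels = c(3L, 4L))
  # start from the strongest positive score: a positive score implies at
  # least one positive-weight x positive-activation channel, so the
  # first normalizer is positive and the unit mass is fully delivered
  S <- lemap:::.predict_scores(tn$net, lemap:::.as_image_array(tn$img))[, , 1]
  # a strictly signed score guarantees a positive excitation path at the
  # score layer, hence a positive first normalizer
  if (max(S) > 0) {
    pk <- which(S == max(S), arr.ind = TRUE)[1, ]
    kind <- "max"
  } else {
    pk <- which(S == min(S), arr.ind = TRUE)[1, ]
    kind <- "min"
  }
  out <- propagate_importance(tn$net, tn$img, row = pk[1], col = pk[2],
                              kind = kind)
  expect_true(all(out$map >= 0))
  expect_equal(out$mass, 1, tolerance = 1e-5)
  expect_error(propagate_importance(structure(list(), class = "lm"),
                                    tn$img, 1, 1), "lem_backbone")
  expect_error(propagate_importance(tn$net, tn$img, row = 99, col = 1))
})

test_that("negating projection and scores swaps max and min branches
           exactly", {
  tn <- tiny_net(12, size = 16L, channels = c(3L, 4L))
  fw <- lemap:::.net_forward(tn$net, lemap:::.as_image_array(tn$img))
  neg <- tn$net; neg$proj$V <- -neg$proj$V; neg$proj$b <- -neg$proj$b
  fwn <- lemap:::.net_forward(neg, lemap:::.as_image_array(tn$img))
  expect_equal(fwn$S, -fw$S, tolerance = 1e-12)
  st <- data.frame(row = 3, col = 2, kind = "max")
  stn <- data.frame(row = 3, col = 2, kind = "min")
  a <- lemap:::.propagate(tn$net, fw, st)
  b <- lemap:::.propagate(neg, fwn, stn)
  expect_equal(a$map, b$map, tolerance = 1e-12)
})

test_that("localization is additive over selected extrema", {
  tn <- tiny_net(13, size = 32L, channels = c(3L, 4L))   # 8x8 score map
  fw <- lemap:::.net_forward(tn$net, lemap:::.as_image_array(tn$img))
  s1 <- data.frame(row = 2, col = 2, kind = "max")
  s2 <- data.frame(row = 5, col = 7, kind = "max")
  both <- lemap:::.propagate(tn$net, fw, rbind(s1, s2))
  expect_equal(both$map,
               lemap:::.propagate(tn$net, fw, s1)$map +
                 lemap:::.propagate(tn$net, fw, s2)$map,
               tolerance = 1e-12)
})

test_that("dice and recall definitions", {
  m <- matrix(0, 10, 10); m[2:5, 2:5] <- 1
  expect_equal(dice_coefficient(m, m), 1)
  expect_equal(pixel_recall(m, m), 1)
  disj <- matrix(0, 10, 10); disj[7:9, 7:9] <- 1
  expect_equal(dice_coefficient(m, disj), 0)
  expect_equal(pixel_recall(m, disj), 0)
  # |pred| = |truth| = 100, |intersection| = 50
  pred <- matrix(0, 20, 20); pred[1:100] <- 1
  truth <- matrix(0, 20, 20); truth[51:150] <- 1
  expect_equal(dice_coefficient(pred, truth), 0.5)
  expect_equal(pixel_recall(pred, truth), 0.5)
  expect_equal(dice_coefficient(m * 0, m * 0), 1)   # both empty
})

test_that("binarization thresholds at a fraction of the maximum", {
  map <- matrix(0, 8, 8); map[3, 3] <- 1; map[5, 5] <- 0.1
  r <- binarize_and_score(map, truth = (map > 0.5) * 1,
                          threshold_frac = 0.2)
  expect_equal(sum(r$binary_mask), 1)   # 0.1 < 0.2 * max
  expect_equal(r$dsc, 1)
  expect_equal(r$recall, 1)
  z <- binarize_and_score(map * 0, truth = (map > 0.5) * 1)
  expect_equal(sum(z$binary_mask), 0)
  expect_equal(z$dsc, 0)
})
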