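# Sparse loss (elimination + penalty), cross-entropy losses, the
# blended total objective, and the two schedules.

sig <- function(x) 1 / (1 + exp(-x))

test_that("elimination loss closed forms", {
  S0 <- matrix(0, 5, 7)
  expect_equal(elimination_loss(S0), 5 * 7)  # every cell both max & min
  # k positive maxima and m negative minima, no wrongly signed extrema:
  # an alternating +1/-1 checkerboard has every +1 a maximum and every
  # -1 a minimum
  S <- outer(1:4, 1:4, function(i, j) (-1)^(i + j))
  E <- detect_extrema(S)
  k <- sum(E$smax); m <- sum(E$smin)
  expect_equal(elimination_loss(S, E), 0.5 * (k + m))
})

test_that("a wrongly signed extremum contributes sigma of its score and a
           gradient that pushes it toward the correct sign", {
  # single negative maximum: flat map at -1 except deeper surroundings
  S <- matrix(-3, 5, 5); S[3, 3] <- -1
  E <- detect_extrema(S)
  expect_equal(E$smax[3, 3], 1)
  # its elimination term is sigma(min(-1,0)) = sigma(-1)
  base <- elimination_loss(S, E)
  expect_equal(sig(-1), 0.2689, tolerance = 2e-4)
  # finite difference: d l_eli / d S[3,3] > 0, so descent lowers the
  # score further away from +... no: raises it toward 0 is wrong sign;
  # the term sigma(min(S,0)) decreases as S decreases
  h <- 1e-6
  Sp <- S; Sp[3, 3] <- Sp[3, 3] + h
  Sm <- S; Sm[3, 3] <- Sm[3, 3] - h
  fd <- (elimination_loss(Sp, E) - elimination_loss(Sm, E)) / (2 * h)
  expect_gt(fd, 0)   # gradient descent pushes the wrong maximum down
  expect_equal(fd, sig(-1) * (1 - sig(-1)), tolerance = 1e-5)
  expect_gt(base, 0)
})

test_that("penalty loss closed forms and saturation band", {
  S0 <- matrix(0, 4, 6)
  expect_equal(penalty_loss(S0, tau = 3), 4 * 6 * 2 * sig(3))
  expect_equal(2 * sig(3), 1.90515, tolerance = 1e-5)
  S1 <- S0; S1[2, 3] <- 5
  expect_equal(penalty_loss(S1, tau = 3),
               (4 * 6 - 1) * 2 * sig(3) + sig(5) + sig(3))
  # gradient: zero inside the band, positive outside
  h <- 1e-6
  fd_at <- function(v) {
    Sp <- S0; Sp[1, 1] <- v + h
    Sm <- S0; Sm[1, 1] <- v - h
    (penalty_loss(Sp, 3) - penalty_loss(Sm, 3)) / (2 * h)
  }
  expect_equal(fd_at(2), 0)
  expect_equal(fd_at(-2.5), 0)
  expect_gt(fd_at(5), 0)
  expect_lt(fd_at(-5), 0)  # descent pushes |S| down on both sides
})

test_that("sparse loss composes its two terms", {
  set.seed(51)
  S <- matrix(rnorm(64, sd = 4), 8, 8)
  E <- detect_extrema(S)
  expect_equal(sparse_loss(S, E, gamma = 0), elimination_loss(S, E))
  expect_equal(sparse_loss(matrix(0, 4, 4), gamma = 1, tau = 3),
               16 * (1 + 2 * sig(3)))
  # term-by-term re-evaluation, written out independently
  ref <- sum(E$smax * sig(pmin(S, 0)) + E$smin * sig(-pmax(S, 0))) +
    0.37 * sum(sig(pmax(S, 3)) + sig(-pmin(S, -3)))
  expect_equal(sparse_loss(S, E, gamma = 0.37, tau = 3), ref,
               tolerance = 1e-12)
})

test_that("classification loss is the clipped negative log-likelihood", {
  expect_equal(classification_loss(0.5, 1), log(2))
  expect_equal(classification_loss(0.5, 0), log(2))
  expect_equal(classification_loss(0.9, 1), -log(0.9))
  expect_lt(classification_loss(1 - 1e-9, 1), 1e-6)
  expect_true(is.finite(classification_loss(1, 0)))  # clipped, not Inf
  expect_error(classification_loss(0.5, 2), "t")
})

test_that("total objective is the stated affine combination", {
  expect_equal(total_objective(3, 0.2, 0.7, theta_norm_sq = 10,
                               alpha = 0, mu = 5, lam = 0.01),
               0.7 + 0.005 * 10)
  expect_equal(total_objective(3, 0.2, 0.7, alpha = 1, mu = 0, lam = 0), 0.2)
  set.seed(52)
  for (rep in 1:20) {
    v <- runif(7)
    expect_equal(total_objective(v[1], v[2], v[3], v[4], v[5], v[6], v[7]),
                 v[5] * (v[6] * v[1] + v[2]) + (1 - v[5]) * v[3] +
                   v[7] / 2 * v[4])
  }
})

test_that("loss_terms bundles consistent components", {
  set.seed(53)
  S <- matrix(rnorm(16, sd = 2), 4, 4)
  lt <- loss_terms(S, t = 1, config = lem_config(), alpha = 0.5)
  expect_equal(lt$l_spa, lt$l_eli + 0.1 * lt$l_pna)
  expect_equal(lt$l_lem, classification_loss(lt$y_lem, 1))
  expect_true(all(c(lt$l_eli, lt$l_pna, lt$l_lem, lt$l_gap) >= 0))
  expect_true(is.finite(lt$total_j))
})

test_that("alpha schedule hits its endpoints monotonically", {
  a <- alpha_schedule(0:399, 400)
  expect_equal(a[1], 0.1)
  expect_equal(a[400], 1.0)
  expect_true(all(diff(a) >= 0))
  expect_equal(alpha_schedule(200:399, 400), rep(1, 200))
  expect_error(alpha_schedule(400, 400))
})

test_that("learning-rate schedule decays by 0.98 every eight epochs", {
  lr <- lr_schedule(0:399)
  expect_equal(lr, 1e-4 * 0.98^(floor((0:399) / 8)), tolerance = 1e-15)
  expect_equal(lr[1:8], rep(1e-4, 8))
  expect_equal(lr[9], 1e-4 * 0.98)
})

test_that("one descent step on l_lem alone moves y_lem toward the label", {
  ds <- lem_simulate(4, class_balance = 0.5, seed = 55)
  lab <- lem_labels(ds)
  for (i in c(which(lab == 1)[1], which(lab == 0)[1])) {
    im <- ds$images[[i]]
    set.seed(9)
    net <- lem_backbone(64)
    y0 <- aggregate_extrema(lemap:::.predict_scores(net,
      lemap:::.as_image_array(im))[, , 1])$y_lem
    # one gradient step on l_lem alone (alpha = 1, mu = 0)
    fw <- lemap:::.net_forward(net, lemap:::.as_image_array(im))
    ex <- lemap:::.detect_extrema_batch(fw$S)
    ag <- lemap:::.aggregate_batch(fw$S, ex)
    dS <- lemap:::.objective_grad_S(fw$S, ex, ag, im$label, alpha = 1,
                                    mu = 0, gamma = 0.1, tau = 3, FALSE)
    gr <- lemap:::.net_backward(net, fw, dS)
    net1 <- lemap:::.net_update(net, gr, 0.5)
    y1 <- aggregate_extrema(lemap:::.predict_scores(net1,
      lemap:::.as_image_array(im))[, , 1])$y_lem
    if (im$label == 1) expect_gt(y1, y0) else expect_lt(y1, y0)
  }
})

test_that("a descent step on the sparse loss reduces it when a wrongly
           signed extremum exists", {
  S <- matrix(-2, 6, 6); S[3, 3] <- -0.5; S[5, 5] <- -4.5
  E <- detect_extrema(S)
  expect_equal(E$smax[3, 3], 1)          # a negative maximum (wrong sign)
  l0 <- sparse_loss(S, E, gamma = 0.1, tau = 3)
  g <- lemap:::.objective_grad_S(array(S, c(6, 6, 1)),
                                 list(smax = array(E$smax, c(6, 6, 1)),
                                      smin = array(E$smin, c(6, 6, 1))),
                                 list(y_lem = 0.5, n = sum(E$smax) +
                                        sum(E$smin)),
                                 t = 0.5, alpha = 1, mu = 1, gamma = 0.1,
                                 tau = 3, use_sparse = TRUE)
  # remove the classification component: at y_lem = t = 0.5 it is zero
  S1 <- S - 0.5 * g[, , 1]
  expect_lt(sparse_loss(S1, detect_extrema(S1), gamma = 0.1, tau = 3), l0)
})
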