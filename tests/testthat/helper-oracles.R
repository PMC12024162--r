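# Independent oracles, written naively on purpose: explicit loops and
# direct transcriptions, sharing no code with the implementation paths
# they check.

# Clipped-window extremum scan: for every cell, materialize its 3x3
# window clipped at the boundary (window includes the cell) and compare.
brute_extrema <- function(S) {
  nr <- nrow(S); nc <- ncol(S)
  smax <- smin <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    win <- S[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    if (S[i, j] == max(win)) smax[i, j] <- 1
    if (S[i, j] == min(win)) smin[i, j] <- 1
  }
  list(smax = smax, smin = smin)
}

# Pair-counting AUC: (#concordant + 0.5 #ties) / #pairs over all
# positive-negative pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  num <- 0
  for (p in pos) for (q in neg)
    num <- num + if (p > q) 1 else if (p == q) 0.5 else 0
  num / (length(pos) * length(neg))
}

# Per-position projection by an explicit triple loop.
brute_score_map <- function(M, V, bias = 0) {
  C <- dim(M)[1]; W <- dim(M)[2]; H <- dim(M)[3]
  S <- matrix(0, W, H)
  for (i in seq_len(W)) for (j in seq_len(H)) {
    acc <- bias
    for (c in seq_len(C)) acc <- acc + M[c, i, j] * V[c]
    S[i, j] <- acc
  }
  S
}

# Exhaustive top-down importance propagation on a bundled backbone,
# implemented neuron by neuron with explicit loops.  Activations are
# recomputed here from the weights (forward pass included), so the
# oracle is independent of the package's matrix machinery end to end.
# net: lem_net; img: H x W matrix; starts: data.frame(row, col, kind).
brute_propagate <- function(net, img, starts) {
  H <- nrow(img)
  # forward, layer by layer, as plain arrays (H, W, C)
  acts <- list(array(img - 0.5, dim = c(H, H, 1)))  # centered, as the model
  raw0 <- array(img, dim = c(H, H, 1))              # raw pixel activations
  pre <- list(); pooled <- list()
  a <- acts[[1]]
  for (b in seq_along(net$blocks)) {
    bl <- net$blocks[[b]]
    hh <- dim(a)[1]; cin <- dim(a)[3]; cout <- bl$cout
    z <- array(0, dim = c(hh, hh, cout))
    for (i in seq_len(hh)) for (j in seq_len(hh)) for (co in seq_len(cout)) {
      acc <- bl$b[co]
      for (di in 0:2) for (dj in 0:2) for (ci in seq_len(cin)) {
        si <- i + di - 1; sj <- j + dj - 1
        v <- if (si >= 1 && si <= hh && sj >= 1 && sj <= hh)
          a[si, sj, ci] else 0
        # weight row order: channel fastest, then kernel offset
        acc <- acc + v * bl$W[ci + cin * (di + 3 * dj), co]
      }
      z[i, j, co] <- acc
    }
    pre[[b]] <- z
    r <- pmax(z, 0)
    h2 <- hh / 2
    p <- array(0, dim = c(h2, h2, cout))
    for (i in seq_len(h2)) for (j in seq_len(h2)) for (co in seq_len(cout))
      p[i, j, co] <- max(r[2 * i - 1, 2 * j - 1, co], r[2 * i, 2 * j - 1, co],
                         r[2 * i - 1, 2 * j, co], r[2 * i, 2 * j, co])
    pooled[[b]] <- p
    acts[[b + 1]] <- p
    a <- p
  }
  # importance at the feature-map layer from the chosen extrema
  nb <- length(net$blocks)
  top <- acts[[nb + 1]]
  imp <- array(0, dim = dim(top))
  for (r in seq_len(nrow(starts))) {
    i <- starts$row[r]; j <- starts$col[r]
    wc <- if (starts$kind[r] == "max") pmax(net$proj$V, 0)
          else pmax(-net$proj$V, 0)
    contrib <- wc * top[i, j, ]
    Z <- sum(contrib)
    if (Z > 0) imp[i, j, ] <- imp[i, j, ] + contrib / Z
  }
  # walk down: pooling routes to arg-max taps (ties split), convolution
  # redistributes by positive-weight x activation fractions
  for (b in rev(seq_along(net$blocks))) {
    bl <- net$blocks[[b]]
    r <- pmax(pre[[b]], 0)
    hh <- dim(r)[1]; cout <- bl$cout; cin <- dim(acts[[b]])[3]
    rimp <- array(0, dim = dim(r))
    h2 <- hh / 2
    for (i in seq_len(h2)) for (j in seq_len(h2)) for (co in seq_len(cout)) {
      if (imp[i, j, co] == 0) next
      taps <- rbind(c(2 * i - 1, 2 * j - 1), c(2 * i, 2 * j - 1),
                    c(2 * i - 1, 2 * j), c(2 * i, 2 * j))
      vals <- apply(taps, 1, function(t) r[t[1], t[2], co])
      win <- which(vals == max(vals))
      for (wix in win)
        rimp[taps[wix, 1], taps[wix, 2], co] <-
          rimp[taps[wix, 1], taps[wix, 2], co] +
          imp[i, j, co] / length(win)
    }
    child <- if (b == 1) raw0 else acts[[b]]  # pixels enter raw
    cimp <- array(0, dim = dim(child))
    for (i in seq_len(hh)) for (j in seq_len(hh)) for (co in seq_len(cout)) {
      if (rimp[i, j, co] == 0) next
      Z <- 0
      for (di in 0:2) for (dj in 0:2) for (ci in seq_len(cin)) {
        si <- i + di - 1; sj <- j + dj - 1
        if (si < 1 || si > hh || sj < 1 || sj > hh) next
        w <- max(bl$W[ci + cin * (di + 3 * dj), co], 0)
        Z <- Z + w * child[si, sj, ci]
      }
      if (Z <= 0) next
      for (di in 0:2) for (dj in 0:2) for (ci in seq_len(cin)) {
        si <- i + di - 1; sj <- j + dj - 1
        if (si < 1 || si > hh || sj < 1 || sj > hh) next
        w <- max(bl$W[ci + cin * (di + 3 * dj), co], 0)
        cimp[si, sj, ci] <- cimp[si, sj, ci] +
          rimp[i, j, co] * w * child[si, sj, ci] / Z
      }
    }
    imp <- cimp
  }
  apply(imp, c(1, 2), sum)
}
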