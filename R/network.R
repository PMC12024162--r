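# Dense-algebra CNN primitives.  Activations live in a flat matrix
# layout: an (H*W*N) x C matrix whose rows are ordered (row index
# fastest, then column, then image).  Convolutions become matrix
# products against patch matrices assembled by precomputed row gathers
# (an im2col with an explicit zero-padding sentinel row), so all heavy
# lifting happens in BLAS with no array transposition.

.lemap_cache <- new.env(parent = emptyenv())

# Row-gather indices for a 3x3 (general k) convolution at stride 1 with
# zero padding: for each kernel offset, a vector mapping every output
# position to the source row in the input matrix, or to the sentinel
# (all-zero) row HWN + 1 when the tap falls outside the image.
.conv_idx <- function(H, W, N, k, pad) {
  key <- paste("c", H, W, N, k, pad, sep = "_")
  got <- .lemap_cache[[key]]
  if (!is.null(got)) return(got)
  ivec <- rep.int(seq_len(H), W * N)
  jvec <- rep.int(rep(seq_len(W), each = H), N)
  nvec <- rep(seq_len(N), each = H * W)
  sent <- H * W * N + 1L
  out <- vector("list", k * k)
  for (o in seq_len(k * k)) {
    di <- (o - 1L) %% k
    dj <- (o - 1L) %/% k
    si <- ivec + di - pad
    sj <- jvec + dj - pad
    ok <- si >= 1L & si <= H & sj >= 1L & sj <= W
    r <- si + H * (sj - 1L) + H * W * (nvec - 1L)
    r[!ok] <- sent
    out[[o]] <- r
  }
  .lemap_cache[[key]] <- out
  out
}

# Row indices of the four taps of 2x2 stride-2 max pooling.
.pool_idx <- function(H, W, N) {
  key <- paste("p", H, W, N, sep = "_")
  got <- .lemap_cache[[key]]
  if (!is.null(got)) return(got)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  i2 <- rep.int(seq_len(H2), W2 * N)
  j2 <- rep.int(rep(seq_len(W2), each = H2), N)
  n2 <- rep(seq_len(N), each = H2 * W2)
  base <- function(a, b) (2L * i2 - 1L + a) + H * (2L * j2 - 2L + b) +
    H * W * (n2 - 1L)
  out <- list(base(0L, 0L), base(1L, 0L), base(0L, 1L), base(1L, 1L))
  .lemap_cache[[key]] <- out
  out
}

# Patch matrix: columns ordered (channel fastest, kernel offset slower),
# matching the row order of the weight matrices.
.patches <- function(Am, H, W, N, k, pad) {
  C <- ncol(Am)
  idx <- .conv_idx(H, W, N, k, pad)
  Ap <- rbind(Am, 0)
  P <- matrix(0, H * W * N, k * k * C)
  for (o in seq_len(k * k))
    P[, (o - 1L) * C + seq_len(C)] <- Ap[idx[[o]], , drop = FALSE]
  P
}

# Scatter a patch-matrix gradient back onto the input rows; for a fixed
# kernel offset the position map is injective, so plain indexed addition
# is exact (out-of-image taps accumulate on the discarded sentinel row).
.unpatch <- function(dP, H, W, N, C, k, pad) {
  idx <- .conv_idx(H, W, N, k, pad)
  dXp <- matrix(0, H * W * N + 1L, C)
  for (o in seq_len(k * k)) {
    cols <- (o - 1L) * C + seq_len(C)
    dXp[idx[[o]], ] <- dXp[idx[[o]], , drop = FALSE] +
      dP[, cols, drop = FALSE]
  }
  dXp[seq_len(H * W * N), , drop = FALSE]
}

.maxpool_forward_m <- function(Am, H, W, N) {
  v <- .pool_idx(H, W, N)
  a1 <- Am[v[[1]], , drop = FALSE]; a2 <- Am[v[[2]], , drop = FALSE]
  a3 <- Am[v[[3]], , drop = FALSE]; a4 <- Am[v[[4]], , drop = FALSE]
  list(out = pmax(a1, a2, a3, a4), taps = list(a1, a2, a3, a4))
}

# Gradient (and importance) routing through 2x2 max pooling: each
# pooled value's mass goes to the arg-max tap; exact ties share it
# equally.
.maxpool_backward_m <- function(dY, pool, H, W, N) {
  v <- .pool_idx(H, W, N)
  m <- lapply(pool$taps, function(a) (a == pool$out) * 1)
  cnt <- m[[1]] + m[[2]] + m[[3]] + m[[4]]
  dX <- matrix(0, H * W * N, ncol(dY))
  for (q in 1:4) dX[v[[q]], ] <- dY * m[[q]] / cnt
  dX
}

#' Build the bundled convolutional backbone
#'
#' A plain stack of conv(3x3, same padding) + ReLU + 2x2 max-pool blocks
#' followed by the 1x1 score projection.  Every layer type is supported
#' by the top-down importance propagation of [propagate_importance()].
#' Weights use seeded He-style initialization drawn from the current R
#' random stream; call `set.seed()` beforehand for reproducibility.
#'
#' @param input_size Side length of square input images in pixels.
#' @param channels Integer vector of output channels per block; its length
#'   sets the number of blocks (and halvings of spatial extent).
#' @param in_channels Number of input image channels (1 for grayscale).
#' @return An object of class `lem_net`.
#' @examples
#' set.seed(1)
#' net <- lem_backbone(64)
#' net$score_size
#' @export
lem_backbone <- function(input_size = 64L, channels = c(8L, 16L, 32L),
                         in_channels = 1L) {
  nb <- length(channels)
  score_size <- input_size / 2^nb
  if (score_size != floor(score_size) || score_size < 2)
    stop("input_size ", input_size, " with ", nb,
         " pooling blocks yields a score map smaller than 2x2")
  blocks <- vector("list", nb)
  cin <- in_channels
  for (b in seq_len(nb)) {
    cout <- channels[b]
    Wm <- matrix(stats::rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                 nrow = 9 * cin, ncol = cout)
    blocks[[b]] <- list(W = Wm, b = numeric(cout), k = 3L, pad = 1L,
                        cin = cin, cout = cout)
    cin <- cout
  }
  V <- stats::rnorm(cin, sd = sqrt(1 / cin))
  structure(list(blocks = blocks, proj = list(V = V, b = 0),
                 input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 in_channels = as.integer(in_channels),
                 score_size = as.integer(score_size)),
            class = "lem_net")
}

#' @export
print.lem_net <- function(x, ...) {
  cat(sprintf("LEM backbone: %dx%d input, %d conv blocks (%s channels), %dx%d score map, %d parameters\n",
              x$input_size, x$input_size, length(x$blocks),
              paste(x$channels, collapse = "-"),
              x$score_size, x$score_size, lem_n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters of a backbone
#' @param net A `lem_net` object.
#' @return Integer parameter count (weights and biases).
#' @export
lem_n_parameters <- function(net) {
  n <- length(net$proj$V) + 1L
  for (bl in net$blocks) n <- n + length(bl$W) + length(bl$b)
  n
}

# Squared L2 norm of all weights, biases excluded (the weight-decay term
# of the objective regularizes multiplicative parameters only).
.theta_norm_sq <- function(net) {
  s <- sum(net$proj$V^2)
  for (bl in net$blocks) s <- s + sum(bl$W^2)
  s
}

# Full forward pass on a batch.  x: (H, W, N) array of grayscale images
# in [0, 1] (or (H, W, C, N)).  The network zero-centers its input
# (x - 1/2): with all-positive inputs the first-layer weight gradients
# are nearly collinear and plain SGD stalls.  Centering is part of the
# model, not of the data contract, so stored images stay in [0, 1].
# Returns the score maps plus every intermediate needed by the backward
# pass and by importance propagation.
.net_forward <- function(net, x) {
  if (length(dim(x)) == 3)
    dim(x) <- c(dim(x)[1], dim(x)[2], 1L, dim(x)[3])
  d <- dim(x)
  stopifnot(d[1] == net$input_size, d[3] == net$in_channels)
  H <- d[1]; W <- d[2]; N <- d[4]
  Araw <- if (d[3] == 1L) matrix(as.vector(x), ncol = 1L)
          else matrix(as.vector(aperm(x, c(1, 2, 4, 3))), ncol = d[3])
  Am <- Araw - 0.5
  stages <- vector("list", length(net$blocks))
  for (b in seq_along(net$blocks)) {
    bl <- net$blocks[[b]]
    P <- .patches(Am, H, W, N, bl$k, bl$pad)
    pre <- P %*% bl$W
    pre <- sweep(pre, 2, bl$b, "+")
    r <- pre * (pre > 0)
    pool <- .maxpool_forward_m(r, H, W, N)
    stages[[b]] <- list(P = P, pre = pre, pool = pool,
                        H = H, W = W, N = N, cin = ncol(Am))
    Am <- pool$out
    H <- H %/% 2L; W <- W %/% 2L
  }
  svec <- drop(Am %*% net$proj$V) + net$proj$b
  list(S = array(svec, dim = c(H, W, N)), Mmat = Am, stages = stages,
       Araw = Araw, n = N, score_dim = c(H, W))
}

# Backward pass from the gradient of the loss w.r.t. the score maps.
# dS: (h, w, N) array.  Returns per-layer weight gradients.
.net_backward <- function(net, fw, dS) {
  dSvec <- as.vector(dS)  # rows of Mmat are ordered (i, j, n), like dS
  dV <- drop(crossprod(fw$Mmat, dSvec))
  dpb <- sum(dSvec)
  da <- outer(dSvec, net$proj$V)
  grads <- list(proj = list(dV = dV, db = dpb), blocks = list())
  for (b in rev(seq_along(net$blocks))) {
    bl <- net$blocks[[b]]
    st <- fw$stages[[b]]
    dr <- .maxpool_backward_m(da, st$pool, st$H, st$W, st$N)
    dpre <- dr * (st$pre > 0)
    grads$blocks[[b]] <- list(dW = crossprod(st$P, dpre),
                              db = colSums(dpre))
    if (b > 1) {
      dP <- dpre %*% t(bl$W)
      da <- .unpatch(dP, st$H, st$W, st$N, st$cin, bl$k, bl$pad)
    }
  }
  grads
}

# One SGD step: theta <- theta - lr * grad.  Weight decay is added by the
# caller as part of the objective gradient.
.net_update <- function(net, grads, lr) {
  for (b in seq_along(net$blocks)) {
    net$blocks[[b]]$W <- net$blocks[[b]]$W - lr * grads$blocks[[b]]$dW
    net$blocks[[b]]$b <- net$blocks[[b]]$b - lr * grads$blocks[[b]]$db
  }
  net$proj$V <- net$proj$V - lr * grads$proj$dV
  net$proj$b <- net$proj$b - lr * grads$proj$db
  net
}
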