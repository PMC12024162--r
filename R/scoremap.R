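# The score-map head: a 1x1 projection of the last feature map.  A
# global-average-pooled classifier followed by a linear unit and the 1x1
# projection followed by global average pooling are algebraically the
# same computation; the projection order retains spatial information and
# is the one used throughout this package.

sigmoid <- function(x) 1 / (1 + exp(-x))

.check_feature_map <- function(M) {
  if (length(dim(M)) != 3)
    stop("feature map must be a C x W x H array (channels first)")
  if (!all(is.finite(M))) stop("feature map contains non-finite values")
}

#' Compute the score map from a feature map
#'
#' Projects a `C x W x H` feature map `M` onto a single spatial grid of
#' scores via the channel weight vector `V`:
#' `S[i, j] = sum_c M[c, i, j] * V[c] + bias`.  No activation function is
#' applied, so scores may take either sign; positive scores are evidence
#' for the malignant class, negative scores for the benign class.
#'
#' @param M Numeric array of dimension `C x W x H` (channels first).
#' @param V Numeric vector of length `C`, the 1x1 projection weights
#'   (equivalently, the weights of the linear unit after global average
#'   pooling).
#' @param bias Scalar bias, default 0 (the canonical projection carries
#'   no bias; a transferred linear layer may).
#' @return A `W x H` numeric matrix of scores.
#' @examples
#' M <- array(rnorm(4 * 5 * 5), c(4, 5, 5))
#' S <- score_map(M, rnorm(4))
#' dim(S)
#' @export
score_map <- function(M, V, bias = 0) {
  .check_feature_map(M)
  C <- dim(M)[1]
  if (length(V) != C)
    stop("projection weight length ", length(V),
         " does not match channel count ", C)
  W <- dim(M)[2]; H <- dim(M)[3]
  Mm <- matrix(aperm(M, c(2, 3, 1)), nrow = W * H, ncol = C)
  matrix(drop(Mm %*% V) + bias, nrow = W, ncol = H)
}

#' Classification probability via global average pooling
#'
#' The conventional GAP head: the sigmoid of the spatial mean of the
#' score map, `sigma(mean(S))`.  Identical (to floating-point accuracy)
#' to average-pooling the feature map first and applying the linear unit
#' afterwards.
#'
#' @inheritParams score_map
#' @return A single probability in (0, 1).
#' @examples
#' M <- array(0, c(2, 4, 4))
#' gap_probability(M, c(1, -1))  # 0.5
#' @export
gap_probability <- function(M, V, bias = 0) {
  sigmoid(mean(score_map(M, V, bias)))
}

#' Write a score map as a CSV grid
#'
#' @param S Score-map matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_map <- function(S, path) {
  utils::write.table(S, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Render a matrix as a PNG heatmap
#'
#' Linearly rescales values to `[0, 1]` and writes an 8-bit grayscale
#' PNG; a constant matrix maps to mid-gray.
#'
#' @param x Numeric matrix (score map or importance map).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(x, path) {
  rng <- range(x)
  y <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1])
       else matrix(0.5, nrow(x), ncol(x))
  png::writePNG(y, path)
  invisible(path)
}
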