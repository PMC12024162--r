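# Local extremum detection and aggregation: the LEM head proper.
#
# A position is a local maximum (minimum) when its score equals the
# maximum (minimum) of its neighbourhood, where the neighbourhood is the
# 3x3 window clipped at the map boundary and INCLUDES the position
# itself: 4 cells at corners, 6 on edges, 9 in the interior.  The
# comparison is non-strict, so every cell of a tied plateau is flagged,
# and a cell may be flagged in both maps (e.g. on a constant map).

.window_extreme <- function(S, what = c("max", "min")) {
  what <- match.arg(what)
  fill <- if (what == "max") -Inf else Inf
  d <- dim(S); nr <- d[1]; nc <- d[2]
  three <- length(d) == 3
  P <- if (three) array(fill, dim = c(nr + 2, nc + 2, d[3]))
       else matrix(fill, nr + 2, nc + 2)
  if (three) P[1 + seq_len(nr), 1 + seq_len(nc), ] <- S
  else P[1 + seq_len(nr), 1 + seq_len(nc)] <- S
  out <- NULL
  for (di in 0:2) for (dj in 0:2) {
    sub <- if (three) P[di + seq_len(nr), dj + seq_len(nc), , drop = FALSE]
           else P[di + seq_len(nr), dj + seq_len(nc), drop = FALSE]
    dim(sub) <- d
    out <- if (is.null(out)) sub
           else if (what == "max") pmax(out, sub) else pmin(out, sub)
  }
  out
}

#' Detect local extrema of a score map
#'
#' Produces the two binary sampling maps marking local maxima and local
#' minima of the score map under boundary-clipped neighbourhoods of
#' 4 (corner), 6 (edge) or 9 (interior) cells that include the centre
#' cell.  Comparisons are non-strict: plateau cells are flagged, and a
#' cell can appear in both maps.  The global maximum and minimum always
#' qualify, so each map contains at least one flag.
#'
#' @param S Numeric matrix of scores with at least 2 rows and 2 columns,
#'   all values finite.
#' @return A list of class `lem_extrema` with binary matrices `smax` and
#'   `smin` of the same shape as `S`.
#' @examples
#' S <- matrix(0, 3, 3); S[2, 2] <- 2
#' detect_extrema(S)
#' @export
detect_extrema <- function(S) {
  if (!is.matrix(S)) S <- as.matrix(S)
  if (nrow(S) < 2 || ncol(S) < 2)
    stop("score map must be at least 2x2")
  if (!all(is.finite(S))) stop("score map contains non-finite values")
  structure(list(smax = (S == .window_extreme(S, "max")) * 1,
                 smin = (S == .window_extreme(S, "min")) * 1),
            class = "lem_extrema")
}

# Batch version on an (h, w, N) array; returns arrays of the same shape.
.detect_extrema_batch <- function(Sarr) {
  list(smax = (Sarr == .window_extreme(Sarr, "max")) * 1,
       smin = (Sarr == .window_extreme(Sarr, "min")) * 1)
}

#' Aggregate extremum scores into the LEM probability
#'
#' Only extremum scores enter the classification: positive parts of the
#' flagged maxima form the malignant aggregate `a_m`, negative parts of
#' the flagged minima the benign aggregate `a_b`, and the probability is
#' `sigma((a_m + a_b) / n_extrema)` where `n_extrema` counts all flags
#' (a cell flagged in both maps counts twice, per the literal
#' denominator).
#'
#' @param S Numeric score-map matrix.
#' @param E An `lem_extrema` object from [detect_extrema()] computed on
#'   the same map (computed on the fly when missing).
#' @return A list of class `lem_aggregates` with elements `a_m` (>= 0),
#'   `a_b` (<= 0), `n_extrema` and `y_lem`.
#' @examples
#' S <- matrix(0, 3, 3); S[2, 2] <- 2
#' aggregate_extrema(S)$y_lem  # sigma(2/9)
#' @export
aggregate_extrema <- function(S, E = detect_extrema(S)) {
  stopifnot(inherits(E, "lem_extrema"),
            all(dim(E$smax) == dim(S)))
  a_m <- sum(E$smax * pmax(S, 0))
  a_b <- sum(E$smin * pmin(S, 0))
  n <- sum(E$smax) + sum(E$smin)
  if (n < 1) stop("internal error: no extrema flagged")  # unreachable
  structure(list(a_m = a_m, a_b = a_b, n_extrema = n,
                 y_lem = sigmoid((a_m + a_b) / n)),
            class = "lem_aggregates")
}

# Batched aggregation for training: Sarr, smax, smin are (h, w, N).
# Returns per-image aggregates and the pieces reused by the gradient.
.aggregate_batch <- function(Sarr, ex) {
  n <- apply(ex$smax, 3, sum) + apply(ex$smin, 3, sum)
  a_m <- apply(ex$smax * pmax(Sarr, 0), 3, sum)
  a_b <- apply(ex$smin * pmin(Sarr, 0), 3, sum)
  list(a_m = a_m, a_b = a_b, n = n, y_lem = sigmoid((a_m + a_b) / n))
}

#' Export extremum positions as a data frame
#'
#' One row per flagged extremum with its 0-based grid position, kind and
#' score, suitable for writing to CSV.
#'
#' @param S Score-map matrix.
#' @param E An `lem_extrema` object for `S`.
#' @param id Optional image identifier recycled into an `id` column.
#' @return A data frame with columns `id`, `row`, `col`, `kind`, `score`.
#' @export
extrema_table <- function(S, E = detect_extrema(S), id = NA_character_) {
  mx <- which(E$smax == 1, arr.ind = TRUE)
  mn <- which(E$smin == 1, arr.ind = TRUE)
  data.frame(id = id,
             row = c(mx[, 1], mn[, 1]) - 1L,
             col = c(mx[, 2], mn[, 2]) - 1L,
             kind = rep(c("max", "min"), c(nrow(mx), nrow(mn))),
             score = c(S[mx], S[mn]),
             stringsAsFactors = FALSE)
}
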