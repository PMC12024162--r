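# Lesion localization: selected score-map extrema are propagated
# top-down through the network.  At the score layer a unit of importance
# is distributed over feature channels through the positive part of the
# projection weights (for maxima; the negated weights for minima); at
# every convolution it is redistributed to the layer below in
# proportion to positive-weight x activation fractions, normalized per
# neuron so each propagated extremum carries unit mass; max pooling
# routes importance to each window's arg-max (ties split equally).  A
# neuron whose normalizer is zero drops its incoming mass; this is the
# only way mass can be lost.

#' Select extrema for localization
#'
#' Branches on the LEM probability: when `y_lem` exceeds the decision
#' threshold all flagged maxima with positive scores are selected, and
#' otherwise all flagged minima with negative scores.  The selection can
#' legitimately be empty (e.g. a constant zero score map on the benign
#' branch); this is reported through the `status` attribute rather than
#' an error.
#'
#' @param S Score-map matrix.
#' @param E `lem_extrema` maps for `S`.
#' @param aggregates `lem_aggregates` computed on the same map.
#' @param threshold Decision threshold on `y_lem`, default 0.5.
#' @return A data frame with columns `row`, `col` (1-based grid
#'   positions), `kind` and `score`, with attribute
#'   `status` equal to `"ok"` or `"empty"`.
#' @export
select_extrema <- function(S, E = detect_extrema(S),
                           aggregates = aggregate_extrema(S, E),
                           threshold = 0.5) {
  malignant <- aggregates$y_lem > threshold
  if (malignant) {
    pos <- which(E$smax == 1 & S > 0, arr.ind = TRUE)
    kind <- "max"
  } else {
    pos <- which(E$smin == 1 & S < 0, arr.ind = TRUE)
    kind <- "min"
  }
  out <- if (nrow(pos) > 0)
    data.frame(row = pos[, 1], col = pos[, 2], kind = kind,
               score = S[pos], stringsAsFactors = FALSE)
  else
    data.frame(row = integer(0), col = integer(0),
               kind = character(0), score = numeric(0))
  attr(out, "status") <- if (nrow(out) > 0) "ok" else "empty"
  out
}

# Core propagation: fw is a single-image forward cache, starts a data
# frame with columns row, col, kind.  Returns the pixel map plus the
# mass actually delivered.
.propagate <- function(net, fw, starts) {
  h <- fw$score_dim[1]; w <- fw$score_dim[2]
  stopifnot(all(starts$row >= 1), all(starts$row <= h),
            all(starts$col >= 1), all(starts$col <= w))
  C <- ncol(fw$Mmat)
  Pcur <- matrix(0, h * w, C)
  injected <- 0
  V <- net$proj$V
  for (r in seq_len(nrow(starts))) {
    rowid <- starts$row[r] + h * (starts$col[r] - 1L)
    wc <- if (starts$kind[r] == "max") pmax(V, 0) else pmax(-V, 0)
    contrib <- wc * fw$Mmat[rowid, ]
    Z <- sum(contrib)
    injected <- injected + 1
    if (Z > 0) Pcur[rowid, ] <- Pcur[rowid, ] + contrib / Z
    # Z == 0: no positive excitation path; this extremum's mass is lost
  }
  for (b in rev(seq_along(net$blocks))) {
    bl <- net$blocks[[b]]
    st <- fw$stages[[b]]
    # through max pooling onto the conv/ReLU output grid; ReLU itself is
    # an identity mapping for importance
    Pr <- .maxpool_backward_m(Pcur, st$pool, st$H, st$W, st$N)
    # through the convolution onto its input activations: fractions of
    # positive weight x child activation, normalized per output neuron.
    # Children of the first convolution are pixels; their natural
    # nonnegative activation is the raw [0, 1] intensity (the network
    # zero-centers internally, but importance fractions require
    # nonnegative children).
    Pm <- if (b == 1L) .patches(fw$Araw, st$H, st$W, st$N, bl$k, bl$pad)
          else st$P
    Wpos <- pmax(bl$W, 0)
    Zmat <- Pm %*% Wpos                    # normalizers per output neuron
    R <- ifelse(Zmat > 0, Pr / Zmat, 0)    # zero normalizer drops mass
    Q <- Pm * (R %*% t(Wpos))
    Pcur <- .unpatch(Q, st$H, st$W, st$N, st$cin, bl$k, bl$pad)
  }
  map <- matrix(rowSums(Pcur), net$input_size, net$input_size)
  list(map = map, injected = injected, delivered = sum(map))
}

#' Propagate importance of one extremum to pixel level
#'
#' Runs a forward pass on the image and redistributes one unit of
#' importance from the given score-map position down to the pixels along
#' positive-weight excitation paths (see the module description above).
#' With every traversed normalizer positive the returned map sums to 1;
#' otherwise part of the mass is dropped and the sum is smaller.
#'
#' @param net An `lem_net` (e.g. `fit$net`).
#' @param image Image matrix in `[0, 1]` matching the network input size.
#' @param row,col 1-based score-map position of the extremum.
#' @param kind `"max"` or `"min"`.
#' @return A list with `map` (nonnegative pixel matrix), `mass`
#'   (delivered mass) and `source` (the extremum).
#' @export
propagate_importance <- function(net, image, row, col,
                                 kind = c("max", "min")) {
  if (!inherits(net, "lem_net"))
    stop("importance propagation supports only networks built by lem_backbone()")
  kind <- match.arg(kind)
  arr <- .as_image_array(image)
  fw <- .net_forward(net, arr)
  stopifnot(row >= 1, row <= dim(fw$S)[1], col >= 1, col <= dim(fw$S)[2])
  pr <- .propagate(net, fw, data.frame(row = row, col = col, kind = kind,
                                       stringsAsFactors = FALSE))
  list(map = pr$map, mass = pr$delivered,
       source = data.frame(row = row, col = col, kind = kind))
}

#' Localize lesions in one image
#'
#' The full localization pipeline: forward pass, extremum detection,
#' LEM probability, branch-dependent extremum selection, and importance
#' propagation of every selected extremum, summed into one pixel-level
#' map.
#'
#' @param fit An `lem_fit` (or pass a bare `lem_net` plus `config`).
#' @param image Image matrix, or an `lem_image` record.
#' @param threshold Decision threshold on `y_lem`; defaults to the
#'   fitted configuration's.
#' @return An object of class `lem_localization`: list with `map`
#'   (nonnegative pixel matrix), `extrema` (selected extrema table),
#'   `y_lem`, `n_extrema_used`, `mass` (delivered importance mass),
#'   `mass_conserved` (logical) and `status` (`"ok"` or `"empty"`).
#' @export
localize <- function(fit, image, threshold = NULL) {
  net <- if (inherits(fit, "lem_fit")) fit$net else fit
  if (!inherits(net, "lem_net"))
    stop("importance propagation supports only networks built by lem_backbone()")
  if (is.null(threshold))
    threshold <- if (inherits(fit, "lem_fit"))
      fit$config$decision_threshold else 0.5
  arr <- .as_image_array(image)
  stopifnot(dim(arr)[3] == 1)
  fw <- .net_forward(net, arr)
  S <- fw$S[, , 1]
  E <- detect_extrema(S)
  ag <- aggregate_extrema(S, E)
  sel <- select_extrema(S, E, ag, threshold)
  if (nrow(sel) == 0) {
    map <- matrix(0, dim(arr)[1], dim(arr)[2])
    return(structure(list(map = map, extrema = sel, y_lem = ag$y_lem,
                          n_extrema_used = 0L, mass = 0,
                          mass_conserved = NA, status = "empty"),
                     class = "lem_localization"))
  }
  pr <- .propagate(net, fw, sel)
  structure(list(map = pr$map, extrema = sel, y_lem = ag$y_lem,
                 n_extrema_used = nrow(sel), mass = pr$delivered,
                 mass_conserved = abs(pr$delivered - pr$injected) < 1e-5,
                 status = "ok"),
            class = "lem_localization")
}

#' @export
print.lem_localization <- function(x, ...) {
  cat(sprintf("LEM localization: y_lem=%.3f, %d extrema propagated (%s), mass %.4f%s\n",
              x$y_lem, x$n_extrema_used,
              if (x$n_extrema_used > 0) paste(unique(x$extrema$kind),
                                              collapse = "/") else "none",
              x$mass,
              if (isTRUE(x$mass_conserved)) " (conserved)" else ""))
  invisible(x)
}

#' @export
plot.lem_localization <- function(x, ...) {
  m <- x$map
  graphics::image(t(m)[, nrow(m):1], col = grDevices::hcl.colors(64, "inferno"),
                  axes = FALSE, asp = 1, ...)
  invisible(x)
}

#' Binarize an importance map and score it against ground truth
#'
#' The map is normalized by its maximum and thresholded at a fixed
#' fraction (default 0.2) of the maximum; Dice and recall are computed
#' when a truth mask is supplied.  An all-zero map yields an empty mask
#' with Dice 0 against a nonempty truth.
#'
#' @param map Nonnegative importance matrix.
#' @param truth Optional binary ground-truth mask of the same shape.
#' @param threshold_frac Binarization threshold as a fraction of the map
#'   maximum.
#' @return A list of class `lem_locresult` with `binary_mask` and, when
#'   truth is given, `dsc` and `recall`.
#' @examples
#' m <- matrix(0, 4, 4); m[2, 2] <- 1
#' binarize_and_score(m, truth = m > 0)$dsc
#' @export
binarize_and_score <- function(map, truth = NULL, threshold_frac = 0.2) {
  stopifnot(all(map >= 0))
  mx <- max(map)
  mask <- if (mx > 0) (map >= threshold_frac * mx) * 1 else map * 0
  out <- list(binary_mask = mask, threshold_frac = threshold_frac)
  if (!is.null(truth)) {
    truth <- (truth > 0) * 1
    stopifnot(all(dim(truth) == dim(mask)))
    out$dsc <- dice_coefficient(mask, truth)
    out$recall <- pixel_recall(mask, truth)
  }
  class(out) <- "lem_locresult"
  out
}

#' Dice similarity coefficient between binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty and 0 when exactly one is.
#'
#' @param pred,truth Binary matrices (any nonzero value counts as 1).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  p <- pred > 0; t <- truth > 0
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}

#' Pixel recall of a predicted mask
#'
#' `|pred intersect truth| / |truth|`; defined as 1 for an empty truth.
#'
#' @inheritParams dice_coefficient
#' @return Recall in `[0, 1]`.
#' @export
pixel_recall <- function(pred, truth) {
  p <- pred > 0; t <- truth > 0
  if (sum(t) == 0) return(1)
  sum(p & t) / sum(t)
}

# Binary dilation with a disk of radius r (used when scoring how much
# importance mass falls near the lesion).
.dilate <- function(mask, r) {
  if (r <= 0) return((mask > 0) * 1)
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0, H, W)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= r^2, ]
  m <- (mask > 0) * 1
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    si <- max(1, 1 - di):min(H, H - di)
    sj <- max(1, 1 - dj):min(W, W - dj)
    out[si + di, sj + dj] <- pmax(out[si + di, sj + dj], m[si, sj])
  }
  out
}
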