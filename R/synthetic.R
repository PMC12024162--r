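# Seeded synthetic lesion images.  Each image carries exactly one lesion
# on a textured background: class 0 a radially smooth low-contrast bump,
# class 1 a higher-contrast core with radial spicule ridges.  Lesions
# occupy only a small fraction of the image, emulating the extreme
# foreground sparsity of screening mammograms, and every image comes
# with a pixel ground-truth mask so localization can be scored.

.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

.snap16 <- function(x) round(x * 65535) / 65535

.background <- function(size, noise_sd) {
  ij <- seq_len(size)
  bg <- matrix(0.35, size, size)
  for (k in 1:3) {
    cr <- stats::runif(1, 0.5, 3); cc <- stats::runif(1, 0.5, 3)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.02, 0.08)
    bg <- bg + amp * cos(2 * pi * (outer(ij, ij, function(i, j)
      cr * i / size + cc * j / size)) + ph)
  }
  bg + matrix(stats::rnorm(size^2, sd = noise_sd), size, size)
}

# Lesion intensity field and ground-truth mask for one lesion.
.lesion_field <- function(size, center, radius, kind, contrast, n_spicules) {
  ij <- seq_len(size)
  dx <- outer(ij, rep(1, size)) - center[1]
  dy <- outer(rep(1, size), ij) - center[2]
  d <- sqrt(dx^2 + dy^2)
  if (kind == "benign") {
    L <- contrast * exp(-d^2 / (2 * (radius / 2)^2))
  } else {
    core <- contrast * exp(-d^2 / (2 * (radius / 2.2)^2))
    phi <- atan2(dy, dx)
    base <- stats::runif(1, 0, 2 * pi)
    sp <- matrix(0, size, size)
    for (s in seq_len(n_spicules)) {
      ang <- base + 2 * pi * (s - 1) / n_spicules
      dl <- phi - ang
      along <- d * cos(dl)
      perp <- d * sin(dl)
      ridge <- 0.8 * contrast * exp(-perp^2 / (2 * 0.6^2)) *
        exp(-along^2 / (2 * (0.8 * radius)^2)) * (along > 0)
      sp <- pmax(sp, ridge)
    }
    L <- pmax(core, sp)
  }
  list(field = L, mask = (L > 0.2 * contrast) * 1)
}

.one_image <- function(size, label, noise_sd, max_lesion_frac, id) {
  r_lo <- max(2, size * 3 / 64)
  r_hi <- max(r_lo + 0.5, size * 4.5 / 64)
  radius <- stats::runif(1, r_lo, r_hi)
  margin <- ceiling(2 * radius) + 2
  if (size - 2 * margin < 2)
    stop("image_size ", size, " is too small to contain the minimum lesion")
  center <- c(stats::runif(1, margin + 1, size - margin),
              stats::runif(1, margin + 1, size - margin))
  if (label == 1) {
    contrast <- stats::runif(1, 0.35, 0.6)
    n_sp <- sample(5:9, 1)
    kind <- "malignant"
  } else {
    contrast <- stats::runif(1, 0.15, 0.3)
    n_sp <- 0L
    kind <- "benign"
  }
  les <- .lesion_field(size, center, radius, kind, contrast, n_sp)
  frac <- sum(les$mask) / size^2
  if (frac > max_lesion_frac)
    stop("internal error: lesion mask fraction ", signif(frac, 3),
         " exceeds the configured maximum ", max_lesion_frac)
  px <- .snap16(pmin(pmax(.background(size, noise_sd) + les$field, 0), 1))
  structure(list(pixels = px, label = label, mask = les$mask, id = id,
                 lesion = list(center = center, radius = radius, kind = kind,
                               contrast = contrast, n_spicules = n_sp)),
            class = "lem_image")
}

#' Generate a synthetic lesion dataset
#'
#' Produces `n` seeded grayscale images with binary image-level labels
#' and pixel ground-truth masks.  Exactly `round(n * class_balance)`
#' images are malignant (spiculated, higher contrast); the rest are
#' benign (smooth, lower contrast).  Backgrounds are a sum of three
#' low-frequency cosine gratings with random phase plus i.i.d. Gaussian
#' noise, so images are not trivially thresholdable.  Pixel values are
#' standardized to `[0, 1]` (snapped to the 16-bit grid so that disk
#' round trips are exact).  Identical seeds give bit-identical datasets.
#'
#' @param n Number of images (`n = 0` gives an empty dataset).
#' @param image_size Side length in pixels, at least 32.
#' @param class_balance Fraction of malignant images in `[0, 1]`.
#' @param noise_sd Standard deviation of the additive Gaussian pixel
#'   noise.
#' @param max_lesion_frac Maximum allowed lesion-mask area fraction.
#' @param seed Integer seed.
#' @return An object of class `lem_dataset`: a list with element
#'   `images` (list of `lem_image` records with fields `pixels`,
#'   `label`, `mask`, `id`) and generation metadata.
#' @examples
#' ds <- lem_simulate(4, image_size = 64, seed = 1)
#' sapply(ds$images, `[[`, "label")
#' @export
lem_simulate <- function(n, image_size = 64L, class_balance = 0.5,
                         noise_sd = 0.02, max_lesion_frac = 0.05,
                         seed = 1L) {
  stopifnot(n >= 0, image_size >= 32, class_balance >= 0, class_balance <= 1)
  n <- as.integer(n)
  images <- .with_seed(seed, {
    n_mal <- round(n * class_balance)
    labels <- c(rep(1L, n_mal), rep(0L, n - n_mal))
    if (n > 1) labels <- labels[sample.int(n)]
    lapply(seq_len(n), function(i)
      .one_image(image_size, labels[i], noise_sd, max_lesion_frac,
                 sprintf("img%04d", i)))
  })
  structure(list(images = images, n = n,
                 image_size = as.integer(image_size),
                 class_balance = class_balance, noise_sd = noise_sd,
                 max_lesion_frac = max_lesion_frac, seed = as.integer(seed)),
            class = "lem_dataset")
}

#' @export
print.lem_dataset <- function(x, ...) {
  lab <- lem_labels(x)
  cat(sprintf("Synthetic lesion dataset: %d images (%d malignant, %d benign), %dx%d px, seed %d\n",
              x$n, sum(lab == 1), sum(lab == 0),
              x$image_size, x$image_size, x$seed))
  invisible(x)
}

#' Image-level labels of a dataset
#' @param dataset An `lem_dataset`.
#' @return Integer vector of 0/1 labels.
#' @export
lem_labels <- function(dataset) {
  vapply(dataset$images, function(im) as.integer(im$label), integer(1))
}

# Dataset images stacked into an (H, W, N) array for the network.
.dataset_array <- function(images) {
  if (length(images) == 0) stop("empty image list")
  H <- nrow(images[[1]]$pixels)
  arr <- array(0, dim = c(H, H, length(images)))
  for (i in seq_along(images)) arr[, , i] <- images[[i]]$pixels
  arr
}

# Bilinear rotation about the image centre; border values are clamped to
# the nearest edge pixel.  Used for images (bilinear) and masks
# (nearest neighbour, outside -> 0).
.rotate <- function(m, angle_deg, nearest = FALSE) {
  H <- nrow(m); W <- ncol(m)
  th <- angle_deg * pi / 180
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  io <- outer(seq_len(H), rep(1, W)); jo <- outer(rep(1, H), seq_len(W))
  # inverse map: source coordinates for each output pixel
  si <- cos(th) * (io - ci) + sin(th) * (jo - cj) + ci
  sj <- -sin(th) * (io - ci) + cos(th) * (jo - cj) + cj
  if (nearest) {
    ri <- as.vector(round(si)); rj <- as.vector(round(sj))
    inside <- ri >= 1 & ri <= H & rj >= 1 & rj <= W
    out <- matrix(0, H, W)
    out[inside] <- m[cbind(ri[inside], rj[inside])]
    return(out)
  }
  si <- as.vector(pmin(pmax(si, 1), H)); sj <- as.vector(pmin(pmax(sj, 1), W))
  i0 <- pmin(floor(si), H - 1); j0 <- pmin(floor(sj), W - 1)
  fi <- si - i0; fj <- sj - j0
  v00 <- m[cbind(i0, j0)];     v10 <- m[cbind(i0 + 1, j0)]
  v01 <- m[cbind(i0, j0 + 1)]; v11 <- m[cbind(i0 + 1, j0 + 1)]
  out <- (1 - fi) * (1 - fj) * v00 + fi * (1 - fj) * v10 +
    (1 - fi) * fj * v01 + fi * fj * v11
  matrix(out, H, W)
}

#' Randomly augment a labeled image
#'
#' Applies the training-time augmentation chain: random horizontal
#' flip, rotation uniform in `[-max_angle, max_angle]` degrees,
#' contrast jitter, gamma jitter (the single-channel analogue of a
#' saturation adjustment) and additive Gaussian noise.  The label is
#' preserved and the mask undergoes exactly the same geometric
#' transforms as the pixels (nearest-neighbour resampling).  With all
#' transforms disabled the input is returned unchanged.
#'
#' @param image An `lem_image` record.
#' @param seed Optional integer seed for reproducible draws.
#' @param flip,rotate,contrast,gamma,noise Logical switches for the
#'   individual transforms.
#' @param max_angle Rotation range in degrees.
#' @param noise_sd Standard deviation of the additive noise.
#' @return The augmented `lem_image`, with a `transforms` element
#'   recording the draws actually applied (flip, angle, contrast,
#'   gamma).
#' @export
lem_augment <- function(image, seed = NULL, flip = TRUE, rotate = TRUE,
                        contrast = TRUE, gamma = TRUE, noise = TRUE,
                        max_angle = 30, noise_sd = 0.01) {
  run <- function() {
    px <- image$pixels; mask <- image$mask
    drew <- list(flip = FALSE, angle = 0, contrast = 1, gamma = 1)
    if (flip && stats::runif(1) < 0.5) {
      drew$flip <- TRUE
      px <- px[, rev(seq_len(ncol(px)))]
      if (!is.null(mask)) mask <- mask[, rev(seq_len(ncol(mask)))]
    }
    if (rotate) {
      drew$angle <- stats::runif(1, -max_angle, max_angle)
      px <- .rotate(px, drew$angle)
      if (!is.null(mask)) mask <- .rotate(mask, drew$angle, nearest = TRUE)
    }
    if (contrast) {
      drew$contrast <- stats::runif(1, 0.8, 1.25)
      px <- mean(px) + (px - mean(px)) * drew$contrast
    }
    if (gamma) {
      drew$gamma <- stats::runif(1, 0.8, 1.25)
      px <- pmin(pmax(px, 0), 1)^drew$gamma
    }
    if (noise)
      px <- px + matrix(stats::rnorm(length(px), sd = noise_sd),
                        nrow(px), ncol(px))
    image$pixels <- pmin(pmax(px, 0), 1)
    image$mask <- mask
    image$transforms <- drew
    image
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}
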