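# Training: plain stochastic gradient descent on the blended objective,
# exactly as the update rule is written: theta <- theta - lr * dJ/dtheta.
# The blending weight alpha ramps from GAP-dominated to LEM-dominated,
# the learning rate decays stepwise, and every loss term is logged per
# epoch.

.as_image_array <- function(newdata) {
  if (inherits(newdata, "lem_dataset")) return(.dataset_array(newdata$images))
  if (inherits(newdata, "lem_image")) {
    a <- newdata$pixels; dim(a) <- c(dim(a), 1L); return(a)
  }
  if (is.list(newdata)) return(.dataset_array(newdata))
  if (is.matrix(newdata)) { dim(newdata) <- c(dim(newdata), 1L); return(newdata) }
  if (is.array(newdata) && length(dim(newdata)) == 3) return(newdata)
  stop("cannot interpret 'newdata' as images")
}

# Forward a possibly large image array in batches; returns (h, w, N)
# score maps.
.predict_scores <- function(net, arr, batch_size = 32L) {
  N <- dim(arr)[3]
  hs <- net$score_size
  S <- array(0, dim = c(hs, hs, N))
  i <- 1L
  while (i <= N) {
    j <- min(i + batch_size - 1L, N)
    fw <- .net_forward(net, arr[, , i:j, drop = FALSE])
    S[, , i:j] <- fw$S
    i <- j + 1L
  }
  S
}

#' Fit a local extremum mapping classifier
#'
#' Trains the bundled convolutional backbone with the LEM head on a
#' labeled dataset by plain stochastic gradient descent on the blended
#' objective
#' `J = alpha (mu L_spa + L_lem) + (1 - alpha) L_gap + (lambda/2)||theta||^2`.
#' Extremum indicator maps are constants of each forward pass; gradients
#' flow through the selected score values.  The run is fully determined
#' by `config$seed`.
#'
#' @param dataset An [lem_simulate()] dataset, or any list of
#'   `lem_image` records containing both classes.
#' @param config A [lem_config()]; see [lem_benchmark_config()] for the
#'   desk-scale defaults used in the package's examples.
#' @return An object of class `lem_fit` with components `net` (the
#'   trained `lem_net`), `config`, and `history` (one row per epoch with
#'   every loss term, `alpha` and `lr`).
#' @examples
#' ds <- lem_simulate(16, seed = 1)
#' fit <- lem(ds, lem_benchmark_config(seed = 1, max_epochs = 2,
#'                                     batch_size = 8))
#' fit$history$total_j
#' @export
lem <- function(dataset, config = lem_benchmark_config()) {
  images <- if (inherits(dataset, "lem_dataset")) dataset$images else dataset
  n <- length(images)
  if (n == 0) stop("empty dataset")
  labels <- vapply(images, function(im) as.numeric(im$label), numeric(1))
  if (length(unique(labels)) < 2)
    stop("dataset contains a single class; both classes are required")
  size <- nrow(images[[1]]$pixels)
  hist_rows <- vector("list", config$max_epochs)
  net <- NULL
  vel <- NULL  # momentum velocity, same shape as the gradients
  .with_seed(config$seed, {
    net <- lem_backbone(size, config$channels)
    for (epoch in 0:(config$max_epochs - 1)) {
      lr <- lr_schedule(epoch, config$lr, config$lr_decay,
                        config$lr_decay_every)
      alpha <- alpha_schedule(epoch, config$max_epochs, config$alpha_start,
                              config$alpha_end, config$alpha_ramp)
      ord <- sample.int(n)
      acc <- c(l_eli = 0, l_pna = 0, l_spa = 0, l_lem = 0, l_gap = 0,
               total_j = 0)
      i <- 1L
      while (i <= n) {
        j <- min(i + config$batch_size - 1L, n)
        idx <- ord[i:j]
        batch <- images[idx]
        if (config$augment)
          batch <- lapply(batch, lem_augment)
        x <- .dataset_array(batch)
        t <- labels[idx]
        nb <- length(idx)
        fw <- .net_forward(net, x)
        ex <- .detect_extrema_batch(fw$S)
        ag <- .aggregate_batch(fw$S, ex)
        y_gap <- sigmoid(apply(fw$S, 3, mean))
        tns <- .theta_norm_sq(net)
        l_eli <- sum(ex$smax * sigmoid(pmin(fw$S, 0)) +
                       ex$smin * sigmoid(-pmax(fw$S, 0))) / nb
        l_pna <- sum(sigmoid(pmax(fw$S, config$tau)) +
                       sigmoid(-pmin(fw$S, -config$tau))) / nb
        l_spa <- if (config$use_sparse_loss) l_eli + config$gamma * l_pna else 0
        l_lem <- mean(classification_loss(ag$y_lem, t))
        l_gap <- mean(classification_loss(y_gap, t))
        tot <- total_objective(l_spa, l_lem, l_gap, tns, alpha,
                               config$mu, config$lam)
        if (!is.finite(tot))
          stop(sprintf("non-finite objective at epoch %d (l_spa=%g, l_lem=%g, l_gap=%g); try a smaller learning rate",
                       epoch, l_spa, l_lem, l_gap))
        dS <- .objective_grad_S(fw$S, ex, ag, t, alpha, config$mu,
                                config$gamma, config$tau,
                                config$use_sparse_loss) / nb
        grads <- .net_backward(net, fw, dS)
        for (b in seq_along(net$blocks))
          grads$blocks[[b]]$dW <- grads$blocks[[b]]$dW +
            config$lam * net$blocks[[b]]$W
        grads$proj$dV <- grads$proj$dV + config$lam * net$proj$V
        if (config$momentum > 0) {
          vel <- if (is.null(vel)) grads else list(
            proj = list(
              dV = config$momentum * vel$proj$dV + grads$proj$dV,
              db = config$momentum * vel$proj$db + grads$proj$db),
            blocks = lapply(seq_along(grads$blocks), function(b) list(
              dW = config$momentum * vel$blocks[[b]]$dW + grads$blocks[[b]]$dW,
              db = config$momentum * vel$blocks[[b]]$db + grads$blocks[[b]]$db)))
          net <- .net_update(net, vel, lr)
        } else {
          net <- .net_update(net, grads, lr)
        }
        w <- nb / n
        acc <- acc + w * c(l_eli, l_pna, l_spa, l_lem, l_gap, tot)
        i <- j + 1L
      }
      hist_rows[[epoch + 1]] <- data.frame(
        epoch = epoch, l_eli = acc[["l_eli"]], l_pna = acc[["l_pna"]],
        l_spa = acc[["l_spa"]], l_lem = acc[["l_lem"]],
        l_gap = acc[["l_gap"]], total_j = acc[["total_j"]],
        alpha = alpha, lr = lr)
    }
  })
  structure(list(net = net, config = config,
                 history = do.call(rbind, hist_rows),
                 n_train = n, image_size = size),
            class = "lem_fit")
}

#' Predict from a fitted LEM model
#'
#' @param object An `lem_fit`.
#' @param newdata An `lem_dataset`, a list of `lem_image` records, a
#'   single image matrix, or an `(H, W, N)` array.
#' @param mode `"lem"` for the extremum-aggregation probability,
#'   `"gap"` for the global-average-pooling probability.
#' @param type `"prob"` (default) for a probability vector, `"class"`
#'   for 0/1 labels at the configured decision threshold, `"full"` for a
#'   per-image list carrying the probability, score map and extremum
#'   maps.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.lem_fit <- function(object, newdata,
                            mode = c("lem", "gap"),
                            type = c("prob", "class", "full"), ...) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  arr <- .as_image_array(newdata)
  S <- .predict_scores(object$net, arr, object$config$batch_size)
  N <- dim(S)[3]
  if (type == "full") {
    return(lapply(seq_len(N), function(i) {
      Si <- S[, , i]
      E <- detect_extrema(Si)
      ag <- aggregate_extrema(Si, E)
      list(prob = if (mode == "lem") ag$y_lem else sigmoid(mean(Si)),
           y_lem = ag$y_lem, y_gap = sigmoid(mean(Si)),
           score_map = Si, extrema = E, aggregates = ag)
    }))
  }
  p <- if (mode == "gap") {
    sigmoid(apply(S, 3, mean))
  } else {
    ex <- .detect_extrema_batch(S)
    .aggregate_batch(S, ex)$y_lem
  }
  if (type == "class") as.integer(p > object$config$decision_threshold) else p
}

#' @export
print.lem_fit <- function(x, ...) {
  cat(sprintf("LEM fit: %d training images (%dx%d), %d epochs\n",
              x$n_train, x$image_size, x$image_size, x$config$max_epochs))
  print(x$net)
  last <- x$history[nrow(x$history), ]
  cat(sprintf("final objective %.4f (l_lem %.4f, l_gap %.4f, l_spa %.4f) at alpha=%.2f\n",
              last$total_j, last$l_lem, last$l_gap, last$l_spa, last$alpha))
  invisible(x)
}

#' @export
summary.lem_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.lem_fit")
}

#' @export
print.summary.lem_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  print(f$config)
  h <- f$history
  rows <- unique(c(1, seq(1, nrow(h), by = 5), nrow(h)))
  cat("loss history (selected epochs):\n")
  print(h[rows, ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.lem_fit <- function(object, ...) {
  list(blocks = lapply(object$net$blocks, function(b) list(W = b$W, b = b$b)),
       projection = object$net$proj)
}

#' @export
plot.lem_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$total_j, h$l_lem, h$l_gap),
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "firebrick", "steelblue"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total J", "L_lem", "L_gap"),
                   col = c("black", "firebrick", "steelblue"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Save or load a fitted model checkpoint
#'
#' The checkpoint is a single-file archive holding the trained weights,
#' the configuration and the full training history.
#'
#' @param fit An `lem_fit`.
#' @param path Checkpoint file path.
#' @return `lem_save` returns `path` invisibly; `lem_load` returns the
#'   restored `lem_fit`.
#' @export
lem_save <- function(fit, path) {
  stopifnot(inherits(fit, "lem_fit"))
  saveRDS(list(format = "lemap-checkpoint-1",
               version = as.character(utils::packageVersion("lemap")),
               fit = unclass(fit)), path)
  invisible(path)
}

#' @rdname lem_save
#' @export
lem_load <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "lemap-checkpoint-1"))
    stop("not a lemap checkpoint: ", path)
  structure(obj$fit, class = "lem_fit")
}
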