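# Classification and localization metrics.  AUC is computed as the
# Mann-Whitney rank statistic with midrank tie handling, which equals
# the area under the ROC curve and is exactly testable against
# exhaustive pair counting.

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUC with midrank tie correction:
#' the probability that a randomly chosen positive scores above a
#' randomly chosen negative, ties counting one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels in `{0, 1}`; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @examples
#' compute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC is undefined when only one class is present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted model on a labeled dataset
#'
#' Computes classification accuracy at the configured decision
#' threshold and AUC over the LEM probabilities, and, for images
#' carrying ground-truth masks, runs the full localization pipeline and
#' reports mean Dice and recall (unweighted means over images).  A
#' per-image table accompanies the summary.
#'
#' @param fit An `lem_fit`.
#' @param dataset An `lem_dataset` or list of `lem_image` records.
#' @param localization Logical; set `FALSE` to skip localization
#'   scoring.
#' @param threshold_frac Binarization fraction passed to
#'   [binarize_and_score()].
#' @return An object of class `lem_metrics`: list with `acc`, `auc`,
#'   `mean_dsc`, `mean_recall` (the latter two `NA` when no masks are
#'   available), `n`, and `per_image` (data frame with columns `id`,
#'   `label`, `y_lem`, `y_gap`, `pred`, `dsc`, `recall`,
#'   `n_extrema_used`, `mass_conserved`).
#' @export
lem_evaluate <- function(fit, dataset, localization = TRUE,
                         threshold_frac = 0.2) {
  images <- if (inherits(dataset, "lem_dataset")) dataset$images else dataset
  labels <- vapply(images, function(im) as.numeric(im$label), numeric(1))
  y_lem <- predict(fit, images, mode = "lem")
  y_gap <- predict(fit, images, mode = "gap")
  pred <- as.integer(y_lem > fit$config$decision_threshold)
  per <- data.frame(
    id = vapply(images, function(im)
      if (is.null(im$id)) NA_character_ else im$id, character(1)),
    label = labels, y_lem = y_lem, y_gap = y_gap, pred = pred,
    dsc = NA_real_, recall = NA_real_,
    n_extrema_used = NA_integer_, mass_conserved = NA,
    stringsAsFactors = FALSE)
  if (localization) {
    for (i in seq_along(images)) {
      if (is.null(images[[i]]$mask)) next
      loc <- localize(fit, images[[i]])
      sc <- binarize_and_score(loc$map, images[[i]]$mask, threshold_frac)
      per$dsc[i] <- if (is.null(sc$dsc)) NA_real_ else sc$dsc
      per$recall[i] <- if (is.null(sc$recall)) NA_real_ else sc$recall
      per$n_extrema_used[i] <- loc$n_extrema_used
      per$mass_conserved[i] <- loc$mass_conserved
    }
  }
  structure(list(
    acc = mean(pred == labels),
    auc = compute_auc(y_lem, labels),
    mean_dsc = if (all(is.na(per$dsc))) NA_real_
               else mean(per$dsc, na.rm = TRUE),
    mean_recall = if (all(is.na(per$recall))) NA_real_
                  else mean(per$recall, na.rm = TRUE),
    n = length(images), per_image = per), class = "lem_metrics")
}

#' @export
print.lem_metrics <- function(x, ...) {
  cat(sprintf("LEM evaluation on %d images\n", x$n))
  cat(sprintf("  accuracy %.3f, AUC %.3f\n", x$acc, x$auc))
  if (!is.na(x$mean_dsc))
    cat(sprintf("  mean DSC %.3f, mean recall %.3f\n",
                x$mean_dsc, x$mean_recall))
  invisible(x)
}

#' Serialize a metric report
#'
#' Writes the summary as JSON and the per-image table as CSV.
#'
#' @param metrics An `lem_metrics` object.
#' @param json_path,csv_path Output paths (`NULL` to skip either).
#' @return `metrics`, invisibly.
#' @export
write_metrics <- function(metrics, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    s <- metrics[c("acc", "auc", "mean_dsc", "mean_recall", "n")]
    jsonlite::write_json(s, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(csv_path))
    utils::write.csv(metrics$per_image, csv_path, row.names = FALSE)
  invisible(metrics)
}
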