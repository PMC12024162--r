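# The training objective: sparse loss (elimination + penalty), the two
# cross-entropy losses, and the blended total.  All terms are evaluated
# per image on the score map; extremum indicator maps are treated as
# constants of the forward pass (they are piecewise constant in the
# scores), while gradients flow through the selected score values.

#' Elimination loss
#'
#' Sum over positions of
#' `smax * sigma(min(S, 0)) + smin * sigma(-max(S, 0))`.  A correctly
#' signed extremum (positive maximum, negative minimum) contributes the
#' gradient-free constant `sigma(0) = 0.5`; a wrongly signed extremum
#' contributes a term whose gradient drives its score toward the correct
#' sign.
#'
#' @param S Score-map matrix.
#' @param E `lem_extrema` maps for `S`.
#' @return Nonnegative scalar.
#' @export
elimination_loss <- function(S, E = detect_extrema(S)) {
  stopifnot(all(dim(E$smax) == dim(S)))
  sum(E$smax * sigmoid(pmin(S, 0)) + E$smin * sigmoid(-pmax(S, 0)))
}

.sigmoid_prime <- function(x) { s <- sigmoid(x); s * (1 - s) }

#' Penalty loss
#'
#' Sum over all positions of `sigma(max(S, tau)) + sigma(-min(S, -tau))`.
#' Constant (zero gradient) wherever `|S| <= tau`; outside that band the
#' gradient pushes `|S|` down, confining non-salient scores to
#' `(-tau, tau)` so that genuine extrema stand out.
#'
#' @param S Score-map matrix.
#' @param tau Positive sparsity threshold.
#' @return Nonnegative scalar.
#' @export
penalty_loss <- function(S, tau = 3) {
  stopifnot(tau > 0)
  sum(sigmoid(pmax(S, tau)) + sigmoid(-pmin(S, -tau)))
}

.penalty_grad <- function(S, tau) {
  .sigmoid_prime(pmax(S, tau)) * (S > tau) -
    .sigmoid_prime(-pmin(S, -tau)) * (S < -tau)
}

#' Sparse loss
#'
#' `elimination_loss + gamma * penalty_loss`.  Both terms are
#' nonnegative, so the L1 norms in the reference formulation reduce to
#' the values themselves.
#'
#' @inheritParams elimination_loss
#' @param gamma Nonnegative penalty factor.
#' @param tau Positive sparsity threshold.
#' @return Nonnegative scalar.
#' @export
sparse_loss <- function(S, E = detect_extrema(S), gamma = 0.1, tau = 3) {
  elimination_loss(S, E) + gamma * penalty_loss(S, tau)
}

#' Binary cross-entropy loss
#'
#' Negative log-likelihood `-(t log y + (1 - t) log(1 - y))`, the
#' quantity the optimizer minimizes.  Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` before taking logs.
#'
#' @param y Predicted probability (vectorized).
#' @param t Binary label in `{0, 1}` (vectorized).
#' @return Nonnegative loss value(s).
#' @examples
#' classification_loss(0.5, 1)  # log(2)
#' @export
classification_loss <- function(y, t) {
  stopifnot(all(t %in% c(0, 1)))
  y <- pmin(pmax(y, 1e-7), 1 - 1e-7)
  -(t * log(y) + (1 - t) * log(1 - y))
}

#' Total training objective
#'
#' `alpha * (mu * l_spa + l_lem) + (1 - alpha) * l_gap +
#' (lam / 2) * theta_norm_sq`.  At `alpha = 0` the objective reduces to
#' the plain GAP cross-entropy (plus weight decay); at `alpha = 1` only
#' the LEM path and sparse loss remain.
#'
#' @param l_spa,l_lem,l_gap Loss terms.
#' @param theta_norm_sq Squared L2 norm of the regularized parameters.
#' @param alpha Blending weight in `[0, 1]`.
#' @param mu Sparsity factor.
#' @param lam Weight-decay factor.
#' @return Scalar objective value.
#' @export
total_objective <- function(l_spa, l_lem, l_gap, theta_norm_sq = 0,
                            alpha = 1, mu = 1, lam = 1e-5) {
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * (mu * l_spa + l_lem) + (1 - alpha) * l_gap +
    (lam / 2) * theta_norm_sq
}

#' Evaluate all loss terms on one score map
#'
#' Convenience wrapper returning every component of the objective for a
#' single image, as used by the training loop and its logs.
#'
#' @param S Score-map matrix.
#' @param t Binary label.
#' @param config A [lem_config()] object.
#' @param alpha Blending weight for this epoch.
#' @param theta_norm_sq Squared norm of the regularized parameters.
#' @return A list of class `lem_loss_terms` with fields `l_eli`, `l_pna`,
#'   `l_spa`, `l_lem`, `l_gap`, `y_lem`, `y_gap`, `total_j`.
#' @export
loss_terms <- function(S, t, config = lem_config(), alpha = 1,
                       theta_norm_sq = 0) {
  E <- detect_extrema(S)
  ag <- aggregate_extrema(S, E)
  y_gap <- sigmoid(mean(S))
  l_eli <- elimination_loss(S, E)
  l_pna <- penalty_loss(S, config$tau)
  l_spa <- l_eli + config$gamma * l_pna
  l_lem <- classification_loss(ag$y_lem, t)
  l_gap <- classification_loss(y_gap, t)
  structure(list(
    l_eli = l_eli, l_pna = l_pna, l_spa = l_spa,
    l_lem = l_lem, l_gap = l_gap,
    y_lem = ag$y_lem, y_gap = y_gap,
    total_j = total_objective(l_spa, l_lem, l_gap, theta_norm_sq,
                              alpha, config$mu, config$lam)),
    class = "lem_loss_terms")
}

# Gradient of the per-image objective w.r.t. the score map, batched over
# an (h, w, N) array.  Extremum maps and counts are forward-pass
# constants; max(.,0)/min(.,0) clamps use the subgradient 0 at 0.
# The weight-decay term does not depend on S and is added to the weight
# gradients by the caller.
.objective_grad_S <- function(Sarr, ex, ag, t, alpha, mu, gamma, tau,
                              use_sparse) {
  hw <- prod(dim(Sarr)[1:2])
  N <- dim(Sarr)[3]
  y_gap <- sigmoid(apply(Sarr, 3, mean))
  per <- function(v) array(rep(v, each = hw), dim = dim(Sarr))
  # d l_gap / dS = (y_gap - t) / (W H)
  dS <- (1 - alpha) * per((y_gap - t) / hw)
  # d l_lem / dS = (y_lem - t)/n * (smax 1(S>0) + smin 1(S<0))
  sel <- ex$smax * (Sarr > 0) + ex$smin * (Sarr < 0)
  dS <- dS + alpha * per((ag$y_lem - t) / ag$n) * sel
  if (use_sparse && mu > 0) {
    deli <- ex$smax * .sigmoid_prime(pmin(Sarr, 0)) * (Sarr < 0) -
      ex$smin * .sigmoid_prime(-pmax(Sarr, 0)) * (Sarr > 0)
    dpna <- .sigmoid_prime(pmax(Sarr, tau)) * (Sarr > tau) -
      .sigmoid_prime(-pmin(Sarr, -tau)) * (Sarr < -tau)
    dS <- dS + alpha * mu * (deli + gamma * dpna)
  }
  dS
}
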