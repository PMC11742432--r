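# Rank-weighted Noisy-OR pooling. Per-read attention scores are calibrated
# to probabilities with Platt scaling; reads are ranked by probability and
# weighted by a two-peaked Gaussian bump function (peaks at the lowest and
# highest ranks, sigma = 0.1), so the site probability is driven by the most
# and least modified-looking reads and does not saturate with read depth the
# way a plain Noisy-OR does.

#' Platt scaling parameters
#'
#' @param alpha,beta Finite scalars; `alpha` is the scale (unconstrained in
#'   sign), `beta` the offset. Shared across all bags of a model.
#' @return An object of class `platt_params`.
#' @export
platt_params <- function(alpha = 1, beta = 0) {
  stopifnot(is.finite(alpha), is.finite(beta))
  structure(list(alpha = alpha, beta = beta), class = "platt_params")
}

#' Map attention scores to instance probabilities
#'
#' `f_j = 1 / (1 + exp(-alpha * atts_j - beta))`; strictly monotone in the
#' scores when `alpha > 0`.
#'
#' @param atts Numeric vector of attention scores.
#' @param platt A [platt_params()].
#' @return Probabilities in (0, 1), same length as `atts`.
#' @export
platt <- function(atts, platt = platt_params()) {
  if (!all(is.finite(atts))) stop("non-finite attention scores")
  1 / (1 + exp(-platt$alpha * atts - platt$beta))
}

#' Rank-derived Noisy-OR weights
#'
#' Instance probabilities are ranked in ascending order (ties broken stably
#' by instance index), ranks are normalized to `[0, 1]` by dividing by
#' `k - 1`, a two-peaked bump `S(u) = N(u; 0, 0.1) + N(u; 1, 0.1)` (Gaussian
#' densities) scores each normalized rank, and the scores are normalized
#' within the bag to sum to 1. A single-instance bag gets weight 1 by
#' convention (the normalized rank is undefined at k = 1).
#'
#' @param f Instance probabilities, length k >= 1.
#' @param sigma Bump standard deviation (default 0.1).
#' @return A list with `ranks` (0-based, a permutation of 0..k-1),
#'   `normalized_ranks`, `raw_S`, and `weights` summing to 1.
#' @export
rank_weights <- function(f, sigma = 0.1) {
  k <- length(f)
  stopifnot(k >= 1L)
  if (k == 1L) {
    return(list(ranks = 0L, normalized_ranks = NA_real_,
                raw_S = NA_real_, weights = 1))
  }
  ranks <- integer(k)
  ranks[order(f, seq_len(k))] <- seq_len(k) - 1L
  u <- ranks / (k - 1)
  S <- dnorm(u, 0, sigma) + dnorm(u, 1, sigma)
  list(ranks = ranks, normalized_ranks = u, raw_S = S,
       weights = S / sum(S))
}

#' Weighted Noisy-OR bag probability
#'
#' `F = 1 - prod_j (1 - f_j)^(w_j)`; permutation invariant, zero iff all
#' instance probabilities are zero, and nondecreasing in each `f_j`.
#' `(1 - f)` is clipped at `eps` before exponentiation.
#'
#' @param f Instance probabilities in `[0, 1]`.
#' @param w Weights summing to 1 (see [rank_weights()]).
#' @param eps Clipping constant.
#' @return Probability scalar.
#' @export
weighted_noisy_or <- function(f, w, eps = 1e-7) {
  stopifnot(length(f) == length(w))
  if (abs(sum(w) - 1) > 1e-6) stop("weights must sum to 1")
  if (any(f < 0 | f > 1)) stop("instance probabilities outside [0, 1]")
  1 - exp(sum(w * log(pmax(1 - f, eps))))
}

#' Standard (unweighted) Noisy-OR bag probability
#'
#' `F = 1 - prod_j (1 - f_j)`: one minus the probability that every instance
#' is negative. Provided as the ablation pooling variant; it converges to 1
#' as bag size grows, the pathology the weighted variant avoids.
#'
#' @inheritParams weighted_noisy_or
#' @return Probability scalar.
#' @export
standard_noisy_or <- function(f, eps = 1e-7) {
  if (any(f < 0 | f > 1)) stop("instance probabilities outside [0, 1]")
  1 - exp(sum(log(pmax(1 - f, eps))))
}

# Dispatch on the pooling variant. `w` is only used by weighted_noisy_or.
pool_bag_prob <- function(f, w, pooling, eps = 1e-7) {
  switch(pooling,
    weighted_noisy_or = weighted_noisy_or(f, w, eps),
    noisy_or = standard_noisy_or(f, eps),
    mean = mean(f),
    max = max(f),
    stop("unknown pooling variant: ", pooling)
  )
}

#' Select reliable negatives among unlabeled bags
#'
#' Returns the `n_pos` unlabeled bags with the lowest predicted positive
#' probability, so the PU task becomes a balanced classification problem
#' (|R| = |P|). Ties at the cutoff are broken by bag id order, making the
#' selection deterministic.
#'
#' @param unlabeled_bag_probs Named numeric vector: bag id -> predicted F(B).
#' @param n_pos Number of bags to select (the number of labeled positives).
#' @return Character vector of selected bag ids.
#' @export
select_reliable_negatives <- function(unlabeled_bag_probs, n_pos) {
  if (length(unlabeled_bag_probs) < n_pos) {
    stop("need at least ", n_pos, " unlabeled bags, have ",
         length(unlabeled_bag_probs))
  }
  ids <- names(unlabeled_bag_probs)
  if (is.null(ids)) stop("unlabeled_bag_probs must be named by bag id")
  ord <- order(unlabeled_bag_probs, ids)
  ids[ord[seq_len(n_pos)]]
}

#' PU loss over positive and reliable-negative bag probabilities
#'
#' `L_p = -[sum log F_pos + sum log(1 - F_relneg)] + lambda (alpha^2 +
#' beta^2)`; the quadratic penalty on the Platt parameters guards against
#' overfitting the calibration.
#'
#' @param F_pos Bag probabilities of the labeled positive bags.
#' @param F_relneg Bag probabilities of the reliable negative bags; must have
#'   the same length as `F_pos` (the balanced-classes contract).
#' @param platt A [platt_params()] (penalized).
#' @param lambda Nonnegative penalty weight.
#' @param eps Clipping constant for the logs.
#' @return Scalar loss.
#' @export
loss_pu <- function(F_pos, F_relneg, platt = platt_params(), lambda = 1e-3,
                    eps = 1e-7) {
  if (length(F_pos) != length(F_relneg)) {
    stop("unbalanced sets: |P| = ", length(F_pos),
         ", |R| = ", length(F_relneg))
  }
  stopifnot(lambda >= 0)
  fp <- pmin(pmax(F_pos, eps), 1 - eps)
  fr <- pmin(pmax(F_relneg, eps), 1 - eps)
  -(sum(log(fp)) + sum(log(1 - fr))) +
    lambda * (platt$alpha^2 + platt$beta^2)
}

#' Total training loss
#'
#' The sum of the MIL classifier loss and the PU pooling loss; both
#' components are logged separately during training.
#'
#' @param L_m MIL loss (see [loss_mil()]).
#' @param L_p PU loss (see [loss_pu()]).
#' @return `L_m + L_p`.
#' @export
total_loss <- function(L_m, L_p) L_m + L_p
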