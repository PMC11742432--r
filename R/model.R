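# Gated-attention multi-instance model: a feed-forward embedding D -> M -> M
# with ReLU, tanh-gated attention pooling (V: L x M, w_att: L), a logistic
# bag classifier on the pooled embedding, and a Platt scaler (alpha, beta)
# that maps per-instance attention scores to modification probabilities.

CHECKPOINT_FORMAT <- "pumil-v1"

#' Initialize an attention MIL model
#'
#' Parameters are drawn from Glorot-style uniform ranges under the given seed,
#' so two models built with the same dimensions and seed are identical.
#'
#' @param input_dim Instance feature dimension D (40 for the m6A front end).
#' @param hidden_dim Embedding dimension M.
#' @param attention_dim Attention dimension L.
#' @param pooling Bag-probability pooling variant, one of
#'   `"weighted_noisy_or"` (default), `"noisy_or"`, `"mean"`, `"max"`.
#' @param attention Either `"gated_tanh"` (default) or `"none"`; with
#'   `"none"` the pooled embedding uses uniform 1/k weights (mean pooling),
#'   the attention-removal ablation.
#' @param seed Integer seed for initialization.
#' @return An object of class `pum6a_model`.
#' @export
mil_model <- function(input_dim, hidden_dim = 16L, attention_dim = 8L,
                      pooling = c("weighted_noisy_or", "noisy_or",
                                  "mean", "max"),
                      attention = c("gated_tanh", "none"), seed = 1L) {
  pooling <- match.arg(pooling)
  attention <- match.arg(attention)
  D <- as.integer(input_dim); M <- as.integer(hidden_dim)
  L <- as.integer(attention_dim)
  stopifnot(D >= 1L, M >= 1L, L >= 1L)
  glorot <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -r, r), nr, nc)
  }
  params <- local_seed(seed, list(
    W1 = glorot(D, M), b1 = numeric(M),
    W2 = glorot(M, M), b2 = numeric(M),
    V = glorot(L, M), w_att = as.numeric(glorot(L, 1L)),
    w_cls = as.numeric(glorot(M, 1L)),
    alpha = 1, beta = 0
  ))
  structure(
    list(params = params, dims = list(D = D, M = M, L = L),
         pooling = pooling, attention = attention, seed = as.integer(seed),
         standardize = NULL, bag_normalize = "none"),
    class = "pum6a_model"
  )
}

# Per-bag baseline correction applied before global standardization.
# "signal_quartile" subtracts, from each signal median and mean column
# (positions 1..20 of the 40-feature m6A schema), the bag's 25th percentile
# of that column: at stoichiometry below ~0.75 the lower quartile of the
# covering reads approximates the unmodified current level of the site's
# kmer context, so the corrected values measure each read's deviation from
# the site baseline rather than the kmer-dependent absolute current.
bag_normalize_apply <- function(X, method) {
  if (is.null(method) || method == "none") return(X)
  if (method == "signal_quartile") {
    cols <- seq(1L, min(19L, ncol(X)), by = 2L)   # median & mean entries
    base <- apply(X[, cols, drop = FALSE], 2L, quantile, probs = 0.25,
                  names = FALSE)
    X[, cols] <- sweep(X[, cols, drop = FALSE], 2L, base, `-`)
    return(X)
  }
  stop("unknown bag_normalize method: ", method)
}

#' @export
print.pum6a_model <- function(x, ...) {
  cat(sprintf(
    "pum6a_model: D=%d -> M=%d (L=%d), pooling=%s, attention=%s\n",
    x$dims$D, x$dims$M, x$dims$L, x$pooling, x$attention))
  invisible(x)
}

relu <- function(x) x * (x > 0)

#' Embed instance feature vectors
#'
#' Applies the two-layer feed-forward embedding to each row of `x`.
#'
#' @param x Numeric vector of length D or a k x D matrix of instances.
#' @param model A [mil_model()].
#' @return A k x M matrix of embeddings (1 x M for a vector input).
#' @export
embed <- function(x, model) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$dims$D) {
    stop("feature dimension mismatch: expected ", model$dims$D,
         ", got ", ncol(x))
  }
  if (!all(is.finite(x))) stop("non-finite features")
  p <- model$params
  h1 <- relu(sweep(x %*% p$W1, 2L, p$b1, `+`))
  relu(sweep(h1 %*% p$W2, 2L, p$b2, `+`))
}

#' Attention scores for a bag of embeddings
#'
#' `atts_j = w_att' tanh(V h_j)`, computed per instance; permutation-
#' equivariant.
#'
#' @param H k x M embedding matrix.
#' @param model A [mil_model()].
#' @return Numeric vector of length k.
#' @export
attention_scores <- function(H, model) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1L)
  if (ncol(H) != model$dims$M) {
    stop("embedding dimension mismatch: expected ", model$dims$M,
         ", got ", ncol(H))
  }
  as.numeric(tanh(H %*% t(model$params$V)) %*% model$params$w_att)
}

#' Softmax attention weights
#'
#' Normalizes attention scores to a probability vector so pooling is
#' invariant to bag size. Computed after max-subtraction for stability;
#' invariant to adding a constant to all scores.
#'
#' @param atts Numeric vector of attention scores.
#' @return Nonnegative weights summing to 1.
#' @export
attention_weights <- function(atts) {
  e <- exp(atts - max(atts))
  e / sum(e)
}

#' Pool a bag of embeddings with attention weights
#'
#' @param H k x M embedding matrix.
#' @param a Weight vector of length k summing to 1.
#' @return The pooled embedding z = sum_j a_j h_j, length M.
#' @export
pool <- function(H, a) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1L)
  stopifnot(length(a) == nrow(H))
  if (abs(sum(a) - 1) > 1e-6) stop("attention weights must sum to 1")
  as.numeric(crossprod(H, a))
}

#' Bag classifier score
#'
#' Logistic score of the pooled embedding, `P = sigmoid(w_cls . z)`;
#' strictly inside (0, 1).
#'
#' @param z Pooled embedding, length M.
#' @param model A [mil_model()].
#' @return Probability scalar.
#' @export
bag_score <- function(z, model) {
  if (!all(is.finite(z))) stop("non-finite pooled embedding")
  plogis_stable(sum(model$params$w_cls * z))
}

plogis_stable <- function(x) 1 / (1 + exp(-x))

#' Full forward pass over one bag
#'
#' @param X k x D matrix of raw instance features (rows are reads).
#' @param model A [mil_model()].
#' @param standardize Apply the model's stored feature standardization
#'   (default TRUE when present).
#' @return A list with `H` (k x M embeddings), `atts` (attention scores),
#'   `a` (attention weights), `z` (pooled embedding), `P` (bag classifier
#'   probability), `f` (Platt instance probabilities), `w` (rank-derived
#'   Noisy-OR weights), and `F` (pooled bag probability under the model's
#'   pooling variant).
#' @export
bag_forward <- function(X, model, standardize = TRUE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (standardize) {
    X <- bag_normalize_apply(X, model$bag_normalize)
    if (!is.null(model$standardize)) {
      X <- standardize_apply(X, model$standardize)
    }
  }
  H <- embed(X, model)
  atts <- attention_scores(H, model)
  a <- if (model$attention == "none") {
    rep(1 / nrow(H), nrow(H))
  } else {
    attention_weights(atts)
  }
  z <- pool(H, a)
  P <- bag_score(z, model)
  f <- platt(atts, platt_params(model$params$alpha, model$params$beta))
  w <- rank_weights(f)$weights
  F_bag <- pool_bag_prob(f, w, model$pooling)
  list(H = H, atts = atts, a = a, z = z, P = P, f = f, w = w, F = F_bag)
}

#' Bernoulli negative log-likelihood over bag scores
#'
#' Scores are clipped into `[eps, 1 - eps]` before the logs.
#'
#' @param bag_scores Probabilities in (0, 1).
#' @param labels 0/1 bag labels, same length.
#' @param eps Clipping constant (default 1e-7).
#' @return Nonnegative scalar loss (summed, not averaged).
#' @export
loss_mil <- function(bag_scores, labels, eps = 1e-7) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  stopifnot(length(bag_scores) == length(labels))
  p <- pmin(pmax(bag_scores, eps), 1 - eps)
  -sum(labels * log(p) + (1 - labels) * log(1 - p))
}

# -- feature standardization --------------------------------------------------

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sigma <- apply(X, 2L, stats::sd)
  sigma[!is.finite(sigma) | sigma < 1e-12] <- 1
  list(mean = as.numeric(mu), sd = as.numeric(sigma))
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2L, st$mean, `-`), 2L, st$sd, `/`)
}

# -- checkpoint I/O -----------------------------------------------------------

#' Save a model checkpoint
#'
#' Single-file JSON checkpoint embedding the parameters, dimensions, pooling
#' variant, seed and feature standardization, tagged with the format version.
#'
#' @param model A [mil_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    format = CHECKPOINT_FORMAT,
    dims = model$dims,
    pooling = model$pooling,
    attention = model$attention,
    seed = model$seed,
    standardize = model$standardize,
    bag_normalize = model$bag_normalize,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    })
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint written by [save_checkpoint()].
#' @return A `pum6a_model`.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(payload$format, CHECKPOINT_FORMAT)) {
    stop("unsupported checkpoint format: ", payload$format)
  }
  params <- lapply(payload$params, function(p) {
    if (!is.null(p$dim)) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  st <- payload$standardize
  if (!is.null(st)) st <- list(mean = st$mean, sd = st$sd)
  structure(
    list(params = params,
         dims = list(D = payload$dims$D, M = payload$dims$M,
                     L = payload$dims$L),
         pooling = payload$pooling, attention = payload$attention,
         seed = payload$seed, standardize = st,
         bag_normalize = if (is.null(payload$bag_normalize)) "none"
                         else payload$bag_normalize),
    class = "pum6a_model"
  )
}
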