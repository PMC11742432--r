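# Seeded end-to-end PU-MIL training. The objective is L = L_m + L_p: a
# Bernoulli bag-classifier loss over the labeled positives and the current
# reliable negatives, plus a Bernoulli loss on the rank-weighted Noisy-OR
# bag probabilities with a quadratic penalty on the Platt parameters.
# Gradients are derived analytically (the rank-derived Noisy-OR weights are
# treated as constants: ranking is non-differentiable, so the weights are
# recomputed each forward pass but gradients do not flow through the sort).

#' Training configuration
#'
#' @param epochs Number of passes over the training bags.
#' @param learning_rate Adam step size.
#' @param bag_batch_size Bags per mini-batch.
#' @param seed Integer seed governing initialization, reliable-negative
#'   scoring order and batch shuffling.
#' @param lambda Weight of the quadratic penalty on the Platt parameters.
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to the
#'   network weight matrices (not to biases or the Platt parameters, which
#'   have their own penalty). Counters bag memorization on small datasets.
#' @param epsilon_clip Probability clipping constant used inside the losses.
#' @param pooling Bag-probability pooling variant (see [mil_model()]).
#' @param attention `"gated_tanh"` or `"none"` (mean-pooling ablation).
#' @param hidden_dim,attention_dim Network dimensions M and L.
#' @param read_subsample Per-epoch cap on reads per training bag: each epoch
#'   every training bag is represented by a fresh random subset of at most
#'   this many reads. Bags are re-drawn every epoch, so the network cannot
#'   memorize bag identities from read-level noise; scoring and prediction
#'   always use all reads. `Inf` disables subsampling.
#' @param reliable_negative_refresh Re-select reliable negatives every epoch
#'   (default) or once before the first epoch.
#' @param relneg_burnin Number of initial epochs during which the reliable
#'   negatives are a fresh uniform draw of |P| unlabeled bags each epoch
#'   instead of the |P| lowest-scoring ones. A cold model ranks the unlabeled
#'   bags arbitrarily, and training against its own early picks can lock in
#'   a wrong labeling; random rotation lets only the consistent structure of
#'   the labeled positives accumulate. Default 0 (paper behavior from the
#'   first epoch).
#' @param relneg_in_mil Use the reliable negatives as the y = 0 bags of the
#'   MIL classifier loss (default TRUE; they are the only negatives available
#'   in PU mode).
#' @param standardize Z-score features column-wise on the training bags and
#'   store the transform in the model.
#' @param bag_normalize Per-bag baseline correction applied before
#'   standardization: `"none"` (default) or `"signal_quartile"`, which
#'   subtracts the bag's lower quartile from each signal median/mean column
#'   of the 40-feature m6A schema (see [m6a_train_config()]).
#' @param early_stop_patience Stop if the monitored quantity (validation bag
#'   AUC when hidden labels are available, else training loss) fails to
#'   improve for this many epochs. `Inf` disables early stopping.
#' @param n_restarts Number of independent training runs from different
#'   parameter initializations. The PU bootstrap (reliable negatives chosen
#'   by a cold model) occasionally locks onto a poor solution, so with
#'   `n_restarts > 1` a `val_fraction` share of the labeled positives and of
#'   the unlabeled bags is held out, each restart is scored by its PU
#'   validation AUC (held-out positives ranked against held-out unlabeled
#'   bags, the standard label-free PU proxy for discrimination), and the
#'   best-scoring run is kept.
#' @param val_fraction Fraction of labeled-positive and unlabeled bags held
#'   out for restart selection (only used when `n_restarts > 1`).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 40L, learning_rate = 1e-3,
                         bag_batch_size = 16L, seed = 1L, lambda = 1e-3,
                         weight_decay = 1e-3, epsilon_clip = 1e-7,
                         pooling = "weighted_noisy_or",
                         attention = "gated_tanh",
                         hidden_dim = 16L, attention_dim = 8L,
                         read_subsample = 20L,
                         reliable_negative_refresh = TRUE,
                         relneg_burnin = 0L,
                         relneg_in_mil = TRUE,
                         standardize = TRUE,
                         bag_normalize = "none",
                         early_stop_patience = Inf,
                         n_restarts = 1L, val_fraction = 0.25) {
  stopifnot(epochs >= 0L, learning_rate > 0, bag_batch_size >= 1L,
            lambda >= 0, weight_decay >= 0, epsilon_clip > 0,
            epsilon_clip < 0.5)
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         bag_batch_size = as.integer(bag_batch_size), seed = as.integer(seed),
         lambda = lambda, weight_decay = weight_decay,
         epsilon_clip = epsilon_clip, pooling = pooling,
         attention = attention, hidden_dim = as.integer(hidden_dim),
         attention_dim = as.integer(attention_dim),
         read_subsample = read_subsample,
         reliable_negative_refresh = reliable_negative_refresh,
         relneg_burnin = as.integer(relneg_burnin),
         relneg_in_mil = relneg_in_mil, standardize = standardize,
         bag_normalize = bag_normalize,
         early_stop_patience = early_stop_patience,
         n_restarts = as.integer(n_restarts),
         val_fraction = val_fraction),
    class = "train_config"
  )
}

#' Training configuration tuned for the 40-feature m6A front end
#'
#' [train_config()] with the defaults used for nanopore m6A site calling:
#' per-site lower-quartile signal baseline correction, 300 epochs of Adam at
#' 3e-3 in batches of 8 bags, 15-read per-bag subsampling, mild weight
#' decay, a 50-epoch reliable-negative burn-in and 4 restarts selected by
#' PU validation AUC. Override any field via `...`.
#'
#' @param ... Overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
m6a_train_config <- function(...) {
  defaults <- list(epochs = 300L, learning_rate = 3e-3, bag_batch_size = 8L,
                   weight_decay = 0.1, read_subsample = 15L,
                   bag_normalize = "signal_quartile", relneg_burnin = 50L,
                   n_restarts = 4L)
  args <- list(...)
  do.call(train_config, utils::modifyList(defaults, args))
}

config_hash <- function(config) {
  s <- paste(vapply(config, function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "|")
  # small deterministic string hash (djb2), hex-encoded
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

bag_feature_matrix <- function(bag) {
  do.call(rbind, lapply(bag$instances, function(i) i$features))
}

# -- forward/backward over one bag -------------------------------------------

bag_forward_cache <- function(X, model, eps = 1e-7) {
  p <- model$params
  A1 <- sweep(X %*% p$W1, 2L, p$b1, `+`); H1 <- relu(A1)
  A2 <- sweep(H1 %*% p$W2, 2L, p$b2, `+`); H <- relu(A2)
  Tm <- tanh(H %*% t(p$V))
  atts <- as.numeric(Tm %*% p$w_att)
  a <- if (model$attention == "none") rep(1 / nrow(X), nrow(X))
       else attention_weights(atts)
  z <- as.numeric(crossprod(H, a))
  P <- plogis_stable(sum(p$w_cls * z))
  f <- 1 / (1 + exp(-p$alpha * atts - p$beta))
  w <- rank_weights(f)$weights
  F_bag <- pool_bag_prob(f, w, model$pooling, eps)
  list(X = X, A1 = A1, H1 = H1, A2 = A2, H = H, Tm = Tm, atts = atts,
       a = a, z = z, P = P, f = f, w = w, F = F_bag)
}

zero_grads <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) p * 0 else p * 0)
}

# Backpropagate upstream scalars gP = dL/dP and gF = dL/dF through one bag,
# accumulating into `g` (a gradient list shaped like the parameters).
bag_backward <- function(cache, model, gP, gF, g, eps = 1e-7) {
  p <- model$params
  k <- nrow(cache$X)

  # classifier head
  ds <- gP * cache$P * (1 - cache$P)
  g$w_cls <- g$w_cls + ds * cache$z
  gz <- ds * p$w_cls

  # pooled embedding z = t(H) a
  ga <- as.numeric(cache$H %*% gz)
  gH <- outer(cache$a, gz)

  # bag probability F through the instance probabilities f
  f <- cache$f
  one_mf <- pmax(1 - f, eps)
  gf <- switch(model$pooling,
    weighted_noisy_or = {
      Q <- 1 - cache$F
      out <- gF * Q * cache$w / one_mf
      out[1 - f < eps] <- 0
      out
    },
    noisy_or = {
      Q <- 1 - cache$F
      out <- gF * Q / one_mf
      out[1 - f < eps] <- 0
      out
    },
    mean = rep(gF / k, k),
    max = {
      out <- numeric(k)
      out[which.max(f)] <- gF
      out
    }
  )

  # Platt scaling
  gfraw <- gf * f * (1 - f)
  g$alpha <- g$alpha + sum(gfraw * cache$atts)
  g$beta <- g$beta + sum(gfraw)
  gatts <- p$alpha * gfraw

  # softmax attention weights (skipped under the mean-pooling ablation)
  if (model$attention != "none") {
    gatts <- gatts + cache$a * (ga - sum(ga * cache$a))
  }

  # attention scores atts = Tm w_att
  g$w_att <- g$w_att + as.numeric(crossprod(cache$Tm, gatts))
  gTm <- outer(gatts, p$w_att)

  # Tm = tanh(H V')
  gPre <- gTm * (1 - cache$Tm^2)
  g$V <- g$V + crossprod(gPre, cache$H)
  gH <- gH + gPre %*% p$V

  # embedding stack
  gA2 <- gH * (cache$A2 > 0)
  g$W2 <- g$W2 + crossprod(cache$H1, gA2)
  g$b2 <- g$b2 + colSums(gA2)
  gH1 <- gA2 %*% t(p$W2)
  gA1 <- gH1 * (cache$A1 > 0)
  g$W1 <- g$W1 + crossprod(cache$X, gA1)
  g$b1 <- g$b1 + colSums(gA1)
  g
}

# Loss and gradients over a batch of bags. `y` gives the bag labels (1 for
# labeled positives, 0 for reliable negatives). Both loss components use the
# same bags: L_m through the classifier head P, L_p through the pooled F.
# `pen_frac` scales the Platt penalty so summing over the epoch's batches
# applies it exactly once.
pu_batch_gradients <- function(model, X_list, y, lambda, eps = 1e-7,
                               pen_frac = 1) {
  g <- zero_grads(model$params)
  L_m <- 0; L_p <- 0
  for (i in seq_along(X_list)) {
    cache <- bag_forward_cache(X_list[[i]], model, eps)
    P <- min(max(cache$P, eps), 1 - eps)
    F_bag <- min(max(cache$F, eps), 1 - eps)
    if (y[i] == 1) {
      L_m <- L_m - log(P); L_p <- L_p - log(F_bag)
      gP <- if (cache$P > eps && cache$P < 1 - eps) -1 / P else 0
      gF <- if (cache$F > eps && cache$F < 1 - eps) -1 / F_bag else 0
    } else {
      L_m <- L_m - log(1 - P); L_p <- L_p - log(1 - F_bag)
      gP <- if (cache$P > eps && cache$P < 1 - eps) 1 / (1 - P) else 0
      gF <- if (cache$F > eps && cache$F < 1 - eps) 1 / (1 - F_bag) else 0
    }
    g <- bag_backward(cache, model, gP, gF, g, eps)
  }
  L_p <- L_p + pen_frac * lambda *
    (model$params$alpha^2 + model$params$beta^2)
  g$alpha <- g$alpha + pen_frac * 2 * lambda * model$params$alpha
  g$beta <- g$beta + pen_frac * 2 * lambda * model$params$beta
  list(grads = g, L_m = L_m, L_p = L_p)
}

# -- Adam ---------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  decayed <- c("W1", "W2", "V", "w_att", "w_cls")
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && nm %in% decayed) {
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
    }
  }
  list(params = params, state = state)
}

# -- training loop ------------------------------------------------------------

#' Train a PU-MIL model on a bag dataset
#'
#' Each epoch: (1) all unlabeled bags are scored with the pooled bag
#' probability F(B); (2) the |P| lowest-scoring unlabeled bags are selected
#' as reliable negatives; (3) L = L_m + L_p is minimized by mini-batch Adam
#' over the labeled positives and reliable negatives. Deterministic under a
#' fixed config (seed included).
#'
#' @param dataset A [pu_bag_dataset()] with at least one labeled positive
#'   and at least one unlabeled bag.
#' @param config A [train_config()].
#' @param val_dataset Optional held-out [pu_bag_dataset()]; when its bags
#'   carry hidden labels, per-epoch validation bag ROC AUC is recorded and
#'   used for early stopping.
#' @param verbose Print per-epoch losses to stderr.
#' @return A list with `model` (a `pum6a_model`) and `report` (class
#'   `train_report`: per-epoch `L`, `L_m`, `L_p`, reliable-negative counts,
#'   validation AUC when available).
#' @export
train_pum6a <- function(dataset, config = train_config(), val_dataset = NULL,
                        verbose = FALSE) {
  if (config$n_restarts <= 1L) {
    return(train_pum6a_once(dataset, config, val_dataset, verbose))
  }
  # PU validation for restart selection: hold out a share of the labeled
  # positives (training drives F of its own positives to 1, so they carry no
  # selection signal) and score each restart by how well it ranks the
  # held-out positives above the unlabeled bags.
  lab <- bag_labels(dataset)
  pos_idx <- which(lab == "positive"); unl_idx <- which(lab == "unlabeled")
  val_pos <- local_seed(config$seed,
    sample(pos_idx, max(1L, round(config$val_fraction * length(pos_idx)))))
  fit_set <- pu_bag_dataset(dataset$bags[-val_pos],
                            label_frequency = dataset$label_frequency)
  val_bags <- dataset$bags[c(val_pos, unl_idx)]
  val_y <- rep(c(1, 0), c(length(val_pos), length(unl_idx)))

  best <- NULL; best_auc <- -Inf; val_aucs <- numeric(config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    cfg_r <- config
    cfg_r$seed <- as.integer((config$seed + (r - 1L) * 100003L) %% 2^31)
    cfg_r$n_restarts <- 1L
    fit <- train_pum6a_once(fit_set, cfg_r, val_dataset, verbose)
    pv <- predict_bags(fit$model, val_bags)
    val_aucs[r] <- roc_pr(pv$sites$site_prob, val_y)$roc_auc
    if (verbose) {
      message(sprintf("restart %d: PU validation AUC=%.4f", r, val_aucs[r]))
    }
    if (val_aucs[r] > best_auc) { best_auc <- val_aucs[r]; best <- fit }
  }
  best$report$restart_pu_val_auc <- val_aucs
  best
}

train_pum6a_once <- function(dataset, config, val_dataset = NULL,
                             verbose = FALSE) {
  lab <- bag_labels(dataset)
  pos_idx <- which(lab == "positive")
  unl_idx <- which(lab == "unlabeled")
  if (length(pos_idx) == 0L) stop("no labeled positive bags")
  if (length(unl_idx) < length(pos_idx)) {
    stop("need at least |P| = ", length(pos_idx), " unlabeled bags, have ",
         length(unl_idx))
  }
  ids <- bag_ids(dataset)
  X_all <- lapply(dataset$bags, bag_feature_matrix)
  D <- ncol(X_all[[1]])

  model <- mil_model(D, config$hidden_dim, config$attention_dim,
                     pooling = config$pooling, attention = config$attention,
                     seed = config$seed)
  model$bag_normalize <- config$bag_normalize
  X_all <- lapply(X_all, bag_normalize_apply, method = config$bag_normalize)
  if (config$standardize) {
    model$standardize <- standardize_fit(do.call(rbind, X_all))
    X_all <- lapply(X_all, standardize_apply, st = model$standardize)
  }
  eps <- config$epsilon_clip

  report <- list(epochs = integer(0), L = numeric(0), L_m = numeric(0),
                 L_p = numeric(0), n_pos = integer(0), n_relneg = integer(0),
                 val_auc = numeric(0), config_hash = config_hash(config))
  class(report) <- "train_report"
  if (config$epochs == 0L) return(list(model = model, report = report))

  opt <- adam_init(model$params)
  relneg_idx <- integer(0)
  best_monitor <- -Inf; stall <- 0L
  val_hidden <- if (!is.null(val_dataset)) hidden_bag_labels(val_dataset)

  local_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      if (epoch <= config$relneg_burnin) {
        relneg_idx <- sample(unl_idx, length(pos_idx))
      } else if (config$reliable_negative_refresh || epoch == 1L ||
                 epoch == config$relneg_burnin + 1L) {
        F_unl <- vapply(unl_idx, function(i) {
          bag_forward_cache(X_all[[i]], model, eps)$F
        }, numeric(1))
        names(F_unl) <- ids[unl_idx]
        rel_ids <- select_reliable_negatives(F_unl, length(pos_idx))
        relneg_idx <- unl_idx[match(rel_ids, ids[unl_idx])]
      }
      stopifnot(length(relneg_idx) == length(pos_idx))  # |R| == |P|

      train_idx <- c(pos_idx, relneg_idx)
      y <- c(rep(1, length(pos_idx)), rep(0, length(relneg_idx)))
      ord <- sample(seq_along(train_idx))
      train_idx <- train_idx[ord]; y <- y[ord]

      batches <- split(seq_along(train_idx),
                       ceiling(seq_along(train_idx) / config$bag_batch_size))
      L_m_ep <- 0; L_p_ep <- 0
      for (b in batches) {
        X_batch <- lapply(X_all[train_idx[b]], function(X) {
          if (nrow(X) <= config$read_subsample) return(X)
          X[sample(nrow(X), config$read_subsample), , drop = FALSE]
        })
        res <- pu_batch_gradients(
          model, X_batch, y[b], config$lambda, eps,
          pen_frac = length(b) / length(train_idx))
        if (!is.finite(res$L_m) || !is.finite(res$L_p)) {
          stop("NaN loss at epoch ", epoch, " (bags ",
               paste(ids[train_idx[b]], collapse = ", "), ")")
        }
        L_m_ep <- L_m_ep + res$L_m; L_p_ep <- L_p_ep + res$L_p
        upd <- adam_step(model$params, res$grads, opt, config$learning_rate,
                         config$weight_decay)
        model$params <- upd$params; opt <- upd$state
      }

      report$epochs <- c(report$epochs, epoch)
      report$L_m <- c(report$L_m, L_m_ep)
      report$L_p <- c(report$L_p, L_p_ep)
      report$L <- c(report$L, total_loss(L_m_ep, L_p_ep))
      report$n_pos <- c(report$n_pos, length(pos_idx))
      report$n_relneg <- c(report$n_relneg, length(relneg_idx))

      monitor <- -report$L[epoch]
      if (!is.null(val_dataset) && !anyNA(val_hidden)) {
        val_pred <- predict_bags(model, val_dataset$bags)
        auc <- roc_pr(val_pred$sites$site_prob, val_hidden)$roc_auc
        report$val_auc <- c(report$val_auc, auc)
        monitor <- auc
      }
      if (verbose) {
        message(sprintf(
          "epoch %d: L=%.4f L_m=%.4f L_p=%.4f |P|=%d |R|=%d%s",
          epoch, report$L[epoch], L_m_ep, L_p_ep, length(pos_idx),
          length(relneg_idx),
          if (length(report$val_auc)) {
            sprintf(" val_auc=%.3f", report$val_auc[epoch])
          } else ""))
      }
      if (monitor > best_monitor + 1e-9) {
        best_monitor <- monitor; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) break
      }
    }
  })
  list(model = model, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  n <- length(x$epochs)
  cat(sprintf("train_report: %d epochs", n))
  if (n > 0) {
    cat(sprintf(", final L=%.4f (L_m=%.4f, L_p=%.4f)",
                x$L[n], x$L_m[n], x$L_p[n]))
    if (length(x$val_auc)) cat(sprintf(", val AUC=%.3f", x$val_auc[n]))
  }
  cat("\n")
  invisible(x)
}

#' Predict site and read probabilities for a collection of bags
#'
#' @param model A trained `pum6a_model`.
#' @param bags List of [site_bag()] objects (or a [pu_bag_dataset()]).
#' @return A list of two data frames, in input order: `sites` with columns
#'   `bag_id`, `n_reads`, `site_prob` (the pooled F(B)) and `cls_prob` (the
#'   bag-classifier head); `reads` with columns `bag_id`, `instance_id`,
#'   `attention`, `read_prob` (Platt-scaled instance probability).
#' @export
predict_bags <- function(model, bags) {
  if (inherits(bags, "pu_bag_dataset")) bags <- bags$bags
  site_rows <- vector("list", length(bags))
  read_rows <- vector("list", length(bags))
  for (i in seq_along(bags)) {
    b <- bags[[i]]
    X <- bag_feature_matrix(b)
    if (ncol(X) != model$dims$D) {
      stop("feature dimension mismatch: model expects ", model$dims$D,
           ", bag '", b$bag_id, "' has ", ncol(X))
    }
    fw <- bag_forward(X, model)
    site_rows[[i]] <- data.frame(
      bag_id = b$bag_id, n_reads = length(b$instances),
      site_prob = fw$F, cls_prob = fw$P, stringsAsFactors = FALSE)
    read_rows[[i]] <- data.frame(
      bag_id = b$bag_id,
      instance_id = vapply(b$instances, function(x) x$instance_id,
                           character(1)),
      attention = fw$a, read_prob = fw$f, stringsAsFactors = FALSE)
  }
  list(sites = do.call(rbind, site_rows),
       reads = do.call(rbind, read_rows))
}
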