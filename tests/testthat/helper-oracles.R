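# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: Gaussian densities, ranking and pooling are
# transcribed directly from their definitions with plain loops.

# direct transcription of the rank -> two-peaked weight -> weighted Noisy-OR
# composition, independent of rank_weights()/weighted_noisy_or()
oracle_gauss <- function(x, mu, sigma) {
  exp(-((x - mu)^2) / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

oracle_rank_weights <- function(f, sigma = 0.1) {
  k <- length(f)
  if (k == 1L) return(1)
  ord <- order(f, seq_len(k))       # ascending, stable by index
  ranks <- integer(k)
  for (r in seq_len(k)) ranks[ord[r]] <- r - 1L
  u <- ranks / (k - 1)
  S <- numeric(k)
  for (j in seq_len(k)) {
    S[j] <- oracle_gauss(u[j], 0, sigma) + oracle_gauss(u[j], 1, sigma)
  }
  S / sum(S)
}

oracle_weighted_noisy_or <- function(f, sigma = 0.1) {
  w <- oracle_rank_weights(f, sigma)
  prod_term <- 1
  for (j in seq_along(f)) prod_term <- prod_term * (1 - f[j])^w[j]
  1 - prod_term
}

# exhaustive pairwise ROC AUC: P(score_pos > score_neg) + 0.5 P(tie)
oracle_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# brute-force PR AUC: precision at each distinct threshold, summed over
# recall increments
oracle_pr_auc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_recall <- 0; auc <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    precision <- tp / sum(pred)
    recall <- tp / n_pos
    auc <- auc + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  auc
}

# small fully-labeled toy bags with a strong, noiseless-ish signal in the
# first coordinate; positives contain n_hot shifted instances
make_toy_bags <- function(n_pos = 10, n_neg = 10, k = 5, d = 4, shift = 4,
                          n_hot = 2, seed = 1) {
  set.seed(seed)
  bags <- list()
  for (b in seq_len(n_pos + n_neg)) {
    positive <- b <= n_pos
    X <- matrix(rnorm(k * d), k, d)
    y <- rep(0, k)
    if (positive) {
      X[seq_len(n_hot), 1] <- X[seq_len(n_hot), 1] + shift
      y[seq_len(n_hot)] <- 1
    }
    inst <- lapply(seq_len(k), function(i) {
      instance_feature(sprintf("b%02d_i%02d", b, i), X[i, ],
                       hidden_label = y[i])
    })
    bags[[b]] <- site_bag(sprintf("b%02d", b), inst)
  }
  bags
}

# hand-built per-read event record
make_events <- function(read_id = "r1",
                        samples = rep(list(c(1, 2, 3)), 5),
                        bases = c("G", "G", "A", "C", "T"),
                        quals = rep(30, 5), ins = rep(0, 5),
                        del = rep(0, 5)) {
  read_site_events(read_id, samples,
                   data.frame(called_base = bases, qual = quals, ins = ins,
                              del = del, stringsAsFactors = FALSE))
}

# the standard synthetic m6A study conditions used by the heavier tests
study_m6a_config <- function(seed, signal_shift_sd = 2, error_inflation = 0.2) {
  m6a_gen_config(n_transcripts = 70L, transcript_length = 300L,
                 n_sites = 200L, prop_modified = 0.5, stoichiometry = 0.5,
                 reads_per_site = c(10L, 30L),
                 signal_shift_sd = signal_shift_sd,
                 error_inflation = error_inflation, seed = seed)
}

# PU scenario with a held-out fold, as used for benchmarking
study_split <- function(dataset, label_frequency, seed) {
  bb <- m6a_bags(dataset, min_reads = 3L)
  pu <- make_pu_scenario(bb$bags, label_frequency, seed = seed)
  pu <- stratified_folds(pu, 5L, seed = seed)
  test_idx <- which(pu$fold_assignments == 0L)
  list(train = pu_bag_dataset(pu$bags[-test_idx], label_frequency),
       test = pu_bag_dataset(pu$bags[test_idx], label_frequency))
}

heldout_aucs <- function(model, dataset) {
  pred <- predict_bags(model, dataset)
  yb <- vapply(dataset$bags, function(b) b$hidden_bag_label, numeric(1))
  yr <- unlist(lapply(dataset$bags, function(b) {
    vapply(b$instances, function(i) i$hidden_label, numeric(1))
  }))
  c(bag = roc_pr(pred$sites$site_prob, yb)$roc_auc,
    instance = roc_pr(pred$reads$read_prob, yr)$roc_auc)
}
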