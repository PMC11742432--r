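#' @importFrom stats dnorm median rnorm runif rbinom rgeom quantile sd ks.test
#' @importFrom utils write.table head
NULL

# -- Domain types -------------------------------------------------------------

#' Create a single-read instance
#'
#' An instance is one read's feature vector at one candidate site. The m6A
#' front end uses D = 40 features (20 signal + 20 alignment); the generic MIL
#' machinery accepts any fixed dimension.
#'
#' @param instance_id Character scalar identifying the read.
#' @param features Numeric vector of fixed length D; all entries finite.
#' @param hidden_label Optional 0/1 read-level label, known only for synthetic
#'   or fully annotated data. `NA` when unknown.
#' @return An object of class `instance_feature`.
#' @export
instance_feature <- function(instance_id, features, hidden_label = NA) {
  stopifnot(is.character(instance_id), length(instance_id) == 1L)
  features <- as.numeric(features)
  if (!all(is.finite(features))) {
    stop("instance '", instance_id, "': non-finite feature values")
  }
  if (!is.na(hidden_label) && !hidden_label %in% c(0, 1)) {
    stop("hidden_label must be 0, 1 or NA")
  }
  structure(
    list(instance_id = instance_id, features = features,
         hidden_label = hidden_label),
    class = "instance_feature"
  )
}

#' Create a site bag
#'
#' A bag is a candidate modification site together with its covering reads.
#' Under the multi-instance assumption the (usually hidden) bag label is 1
#' iff at least one read is modified.
#'
#' @param bag_id Character scalar; site bags use the stable form
#'   `"transcript:position"` so bags stay joinable across pipeline stages.
#' @param instances List of [instance_feature()] objects, length k >= 1.
#' @param bag_label One of `"positive"`, `"unlabeled"`, `"negative"`.
#'   `"negative"` only occurs in fully-labeled evaluation settings.
#' @param hidden_bag_label Optional 0/1 ground-truth bag label. If omitted and
#'   all instances carry hidden labels, it is derived as their OR.
#' @return An object of class `site_bag`.
#' @export
site_bag <- function(bag_id, instances, bag_label = "unlabeled",
                     hidden_bag_label = NA) {
  stopifnot(is.character(bag_id), length(bag_id) == 1L)
  if (length(instances) < 1L) stop("bag '", bag_id, "': needs >= 1 instance")
  if (!all(vapply(instances, inherits, TRUE, "instance_feature"))) {
    stop("instances must be instance_feature objects")
  }
  d <- unique(vapply(instances, function(i) length(i$features), 1L))
  if (length(d) != 1L) {
    stop("bag '", bag_id, "': instances have mixed feature dimensions")
  }
  bag_label <- match.arg(bag_label, c("positive", "unlabeled", "negative"))
  inst_labels <- vapply(instances, function(i) i$hidden_label, numeric(1))
  if (is.na(hidden_bag_label) && !anyNA(inst_labels)) {
    hidden_bag_label <- as.numeric(any(inst_labels == 1))
  }
  if (!is.na(hidden_bag_label) && !anyNA(inst_labels) &&
      hidden_bag_label != as.numeric(any(inst_labels == 1))) {
    stop("bag '", bag_id,
         "': hidden_bag_label contradicts the OR of instance labels")
  }
  structure(
    list(bag_id = bag_id, instances = instances, bag_label = bag_label,
         hidden_bag_label = hidden_bag_label),
    class = "site_bag"
  )
}

#' @export
print.site_bag <- function(x, ...) {
  cat(sprintf("site_bag '%s': %d instances, label=%s, hidden=%s\n",
              x$bag_id, length(x$instances), x$bag_label,
              ifelse(is.na(x$hidden_bag_label), "?", x$hidden_bag_label)))
  invisible(x)
}

#' Assemble a PU bag dataset
#'
#' @param bags List of [site_bag()] objects.
#' @param label_frequency Fraction of true positives carrying a positive label,
#'   in (0, 1]. `NA` when unknown (real data).
#' @param fold_assignments Optional integer vector of per-bag fold indices.
#' @return An object of class `pu_bag_dataset`.
#' @export
pu_bag_dataset <- function(bags, label_frequency = NA,
                           fold_assignments = NULL) {
  if (!all(vapply(bags, inherits, TRUE, "site_bag"))) {
    stop("bags must be site_bag objects")
  }
  if (!is.na(label_frequency) &&
      (label_frequency <= 0 || label_frequency > 1)) {
    stop("label_frequency must be in (0, 1]")
  }
  if (!is.null(fold_assignments) && length(fold_assignments) != length(bags)) {
    stop("fold_assignments length must match number of bags")
  }
  structure(
    list(bags = bags, label_frequency = label_frequency,
         fold_assignments = fold_assignments),
    class = "pu_bag_dataset"
  )
}

#' @export
print.pu_bag_dataset <- function(x, ...) {
  lab <- bag_labels(x)
  cat(sprintf(
    "pu_bag_dataset: %d bags (%d positive, %d unlabeled, %d negative)\n",
    length(x$bags), sum(lab == "positive"), sum(lab == "unlabeled"),
    sum(lab == "negative")))
  if (!is.na(x$label_frequency)) {
    cat(sprintf("  label frequency: %.2f\n", x$label_frequency))
  }
  if (!is.null(x$fold_assignments)) {
    cat(sprintf("  folds: %d\n", length(unique(x$fold_assignments))))
  }
  invisible(x)
}

bag_labels <- function(dataset) {
  vapply(dataset$bags, function(b) b$bag_label, character(1))
}

hidden_bag_labels <- function(dataset) {
  vapply(dataset$bags, function(b) as.numeric(b$hidden_bag_label), numeric(1))
}

bag_ids <- function(dataset) {
  vapply(dataset$bags, function(b) b$bag_id, character(1))
}

# -- PU scenario construction -------------------------------------------------

#' Mask a fully-labeled bag collection into a PU scenario
#'
#' Selects exactly `round(label_frequency * n_positive)` true-positive bags
#' uniformly at random and marks them `"positive"`; every other bag (including
#' all true negatives) becomes `"unlabeled"`. Hidden labels are retained for
#' evaluation only. The exact-count masking makes scenario sizes reproducible
#' at small n, in contrast to per-bag Bernoulli masking.
#'
#' @param bags List of fully-labeled [site_bag()] objects (every bag must have
#'   a hidden bag label).
#' @param label_frequency Fraction in (0, 1] of true positives to label.
#' @param seed Integer seed; the selection is deterministic given the seed.
#' @return A [pu_bag_dataset()].
#' @export
make_pu_scenario <- function(bags, label_frequency, seed) {
  if (label_frequency <= 0 || label_frequency > 1) {
    stop("label_frequency must be in (0, 1]")
  }
  hidden <- vapply(bags, function(b) as.numeric(b$hidden_bag_label), numeric(1))
  if (anyNA(hidden)) stop("all bags must carry hidden_bag_label")
  pos_idx <- which(hidden == 1)
  if (length(pos_idx) == 0L) stop("cannot build PU scenario: no positive bags")
  n_label <- max(1L, round(label_frequency * length(pos_idx)))
  labeled <- local_seed(seed, sample(pos_idx, n_label))
  out <- lapply(seq_along(bags), function(i) {
    b <- bags[[i]]
    b$bag_label <- if (i %in% labeled) "positive" else "unlabeled"
    b
  })
  pu_bag_dataset(out, label_frequency = label_frequency)
}

#' Assign stratified cross-validation folds
#'
#' Bags are stratified on their observed `bag_label` (not the hidden label,
#' which is unavailable in real PU data): within each label class bags are
#' shuffled and dealt round-robin into folds, so per-fold class proportions
#' are within one bag of the global proportions.
#'
#' @param dataset A [pu_bag_dataset()].
#' @param n_folds Number of folds, >= 2.
#' @param seed Integer seed.
#' @return The dataset with `fold_assignments` filled in (0-based fold ids).
#' @export
stratified_folds <- function(dataset, n_folds = 5L, seed = 1L) {
  stopifnot(n_folds >= 2L)
  lab <- bag_labels(dataset)
  folds <- integer(length(lab))
  local_seed(seed, {
    for (cls in unique(lab)) {
      idx <- which(lab == cls)
      if (length(idx) < n_folds) {
        stop("class '", cls, "' has ", length(idx),
             " bags, fewer than n_folds = ", n_folds)
      }
      idx <- sample(idx)
      folds[idx] <- (seq_along(idx) - 1L) %% n_folds
    }
  })
  dataset$fold_assignments <- folds
  dataset
}

# -- Interchange format (long-format TSV, "dialect C") ------------------------

#' Write a bag dataset to the tab-delimited interchange format
#'
#' One row per read: `bag_id`, `instance_id`, `f_0` .. `f_{D-1}`; a companion
#' label table has one row per bag: `bag_id`, `label` coded 1/0/-1 for
#' positive/negative/unlabeled. Features are written with 17 significant
#' digits so the round trip is bit-exact.
#'
#' @param dataset A [pu_bag_dataset()].
#' @param features_path,labels_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_bag_dataset <- function(dataset, features_path, labels_path) {
  rows <- lapply(dataset$bags, function(b) {
    feats <- do.call(rbind, lapply(b$instances, function(i) i$features))
    data.frame(
      bag_id = b$bag_id,
      instance_id = vapply(b$instances, function(i) i$instance_id,
                           character(1)),
      feats, stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  d <- ncol(tab) - 2L
  names(tab) <- c("bag_id", "instance_id", paste0("f_", seq_len(d) - 1L))
  for (j in seq_len(d) + 2L) tab[[j]] <- sprintf("%.17g", tab[[j]])
  write.table(tab, features_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  code <- c(positive = 1L, negative = 0L, unlabeled = -1L)
  lab <- data.frame(bag_id = bag_ids(dataset),
                    label = unname(code[bag_labels(dataset)]))
  write.table(lab, labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(features_path, labels_path))
}

#' Read a bag dataset from the interchange format
#'
#' @param features_path Long-format feature TSV (see [write_bag_dataset()]).
#' @param labels_path Optional label TSV; if missing all bags are unlabeled.
#' @return A [pu_bag_dataset()].
#' @export
read_bag_dataset <- function(features_path, labels_path = NULL) {
  tab <- data.table::fread(features_path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  if (!all(c("bag_id", "instance_id") %in% names(tab))) {
    stop("feature table must have bag_id and instance_id columns")
  }
  fcols <- grep("^f_[0-9]+$", names(tab), value = TRUE)
  if (length(fcols) == 0L) stop("feature table has no f_* columns")
  fcols <- fcols[order(as.integer(sub("^f_", "", fcols)))]
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- data.table::fread(labels_path, sep = "\t", header = TRUE,
                                data.table = FALSE)
    decode <- c(`1` = "positive", `0` = "negative", `-1` = "unlabeled")
    labels$bag_label <- decode[as.character(labels$label)]
  }
  bags <- lapply(split(tab, factor(tab$bag_id, levels = unique(tab$bag_id))),
                 function(g) {
    inst <- lapply(seq_len(nrow(g)), function(i) {
      instance_feature(g$instance_id[i], as.numeric(g[i, fcols]))
    })
    lab <- "unlabeled"
    if (!is.null(labels)) {
      m <- match(g$bag_id[1], labels$bag_id)
      if (!is.na(m)) lab <- labels$bag_label[m]
    }
    site_bag(g$bag_id[1], inst, bag_label = lab)
  })
  pu_bag_dataset(unname(bags))
}

# -- helpers ------------------------------------------------------------------

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
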