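# Synthetic data generators. gen_mil_bags() produces generic fully-labeled
# MIL bags (Gaussian instances, a mean-shifted positive population) for
# benchmarking the PU-MIL machinery. gen_m6a_dataset() emulates the ONT m6A
# setting end to end: transcripts with RRACH sites, per-read raw-signal
# events whose center-base current shifts at modified reads, base-calling
# error inflation, site-level stoichiometry, and writers for the event-table
# dialects, so the whole pipeline is testable without external data.

#' Configuration for the generic MIL bag generator
#'
#' @param n_bags Total number of bags.
#' @param bag_size_range Integer range (lo, hi) of instances per bag.
#' @param instance_dim Feature dimension D.
#' @param positive_bag_rate Fraction of bags that are positive.
#' @param positive_instance_rate Fraction of instances inside a positive bag
#'   drawn from the positive population (at least one is always positive).
#' @param class_separation Mean shift of the positive population along the
#'   first feature, in population-SD units (the background is N(0, 1) per
#'   dimension).
#' @param seed Integer seed.
#' @return An object of class `mil_gen_config`.
#' @export
mil_gen_config <- function(n_bags = 100L, bag_size_range = c(5L, 15L),
                           instance_dim = 10L, positive_bag_rate = 0.5,
                           positive_instance_rate = 0.3,
                           class_separation = 2, seed = 1L) {
  stopifnot(n_bags >= 2L, bag_size_range[1] >= 1L,
            bag_size_range[2] >= bag_size_range[1],
            instance_dim >= 1L, positive_bag_rate > 0,
            positive_bag_rate < 1, class_separation >= 0)
  if (positive_instance_rate <= 0) {
    stop("positive_instance_rate must be > 0: a positive bag must contain ",
         "at least one positive instance")
  }
  structure(as.list(environment()), class = "mil_gen_config")
}

#' Generate fully-labeled generic MIL bags
#'
#' Negative bags draw all instances from a standard Gaussian background;
#' positive bags replace a `positive_instance_rate` fraction (at least one)
#' with instances whose first feature is shifted by `class_separation`
#' population SDs. Hidden instance and bag labels are recorded, and the bag
#' label equals the OR of its instance labels by construction.
#'
#' @param config A [mil_gen_config()].
#' @return List of fully-labeled [site_bag()] objects.
#' @export
gen_mil_bags <- function(config = mil_gen_config()) {
  local_seed(config$seed, {
    n_pos <- round(config$n_bags * config$positive_bag_rate)
    is_pos <- c(rep(TRUE, n_pos), rep(FALSE, config$n_bags - n_pos))
    lapply(seq_len(config$n_bags), function(b) {
      k <- sample(config$bag_size_range[1]:config$bag_size_range[2], 1L)
      X <- matrix(rnorm(k * config$instance_dim), k, config$instance_dim)
      y <- rep(0, k)
      if (is_pos[b]) {
        n_p <- max(1L, round(config$positive_instance_rate * k))
        idx <- sample(k, n_p)
        X[idx, 1] <- X[idx, 1] + config$class_separation
        y[idx] <- 1
      }
      inst <- lapply(seq_len(k), function(i) {
        instance_feature(sprintf("bag%03d_inst%03d", b, i), X[i, ],
                         hidden_label = y[i])
      })
      site_bag(sprintf("bag%03d", b), inst)
    })
  })
}

#' Configuration for the ONT-like m6A dataset generator
#'
#' @param n_transcripts Number of reference transcripts.
#' @param transcript_length Length of each transcript (nt).
#' @param n_sites Optional cap on the number of candidate sites kept (sampled
#'   from all RRACH hits); `NULL` keeps all.
#' @param prop_modified Fraction of candidate sites designated modified.
#' @param stoichiometry Per-site modified-read fraction, a scalar or a
#'   (lo, hi) range sampled per site.
#' @param reads_per_site Integer depth range (lo, hi) sampled per site.
#' @param signal_shift_sd Center-base current-mean shift at modified reads,
#'   in units of the per-base signal SD.
#' @param error_inflation Extra mismatch probability and quality degradation
#'   at the modified center base (0 disables).
#' @param signal_sd Within-read raw-signal SD (pA scale).
#' @param dwell_mean Mean samples per base (geometric dwell model).
#' @param seed Integer seed.
#' @return An object of class `m6a_gen_config`.
#' @export
m6a_gen_config <- function(n_transcripts = 20L, transcript_length = 300L,
                           n_sites = NULL, prop_modified = 0.5,
                           stoichiometry = 0.5, reads_per_site = c(10L, 30L),
                           signal_shift_sd = 2, error_inflation = 0.2,
                           signal_sd = 2.5, dwell_mean = 8, seed = 1L) {
  stopifnot(n_transcripts >= 1L, transcript_length >= 10L,
            prop_modified > 0, prop_modified <= 1,
            all(stoichiometry > 0), all(stoichiometry <= 1),
            reads_per_site[1] >= 1L, signal_shift_sd >= 0,
            error_inflation >= 0, error_inflation <= 1,
            signal_sd > 0, dwell_mean >= 1)
  structure(as.list(environment()), class = "m6a_gen_config")
}

# Deterministic per-kmer current mean (a stand-in pore model): a seeded draw
# from N(85, 8) keyed by the kmer string, independent of the dataset seed.
pore_mean <- function(kmer) {
  h <- 7
  for (ch in utf8ToInt(kmer)) h <- (h * 31 + ch) %% 2^31
  local_seed(h, rnorm(1, 85, 8))
}

#' Generate an ONT-like m6A dataset with known truth
#'
#' Random transcripts are scanned for RRACH sites; a `prop_modified` fraction
#' of sites is designated modified. At a modified site each read is modified
#' with the site's stoichiometry (at least one read is always modified).
#' Modified reads get a `signal_shift_sd`-SD shift of the center-base current
#' mean and, with probability `error_inflation`, a center-base mismatch plus
#' degraded quality. Raw samples follow a per-kmer pore-model mean with
#' geometric dwell.
#'
#' @param config An [m6a_gen_config()].
#' @return An object of class `m6a_dataset`: `sequences` (named character),
#'   `sites` (data frame with `transcript_id`, `center_pos`, `kmer`,
#'   `modified`, `stoichiometry`, `depth`), `events` (nested per-site list of
#'   [read_site_events()]), `read_labels` (named 0/1 vector by read id) and
#'   `config`.
#' @export
gen_m6a_dataset <- function(config = m6a_gen_config()) {
  local_seed(config$seed, {
    seqs <- vapply(seq_len(config$n_transcripts), function(i) {
      paste(sample(c("A", "C", "G", "T"), config$transcript_length,
                   replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("tx%03d", seq_len(config$n_transcripts))

    sites <- do.call(rbind, lapply(names(seqs), function(tx) {
      scan_rrach(seqs[[tx]], tx)
    }))
    if (is.null(sites) || nrow(sites) == 0L) {
      stop("no RRACH sites in generated transcripts; increase length")
    }
    if (!is.null(config$n_sites) && nrow(sites) > config$n_sites) {
      sites <- sites[sort(sample(nrow(sites), config$n_sites)), ,
                     drop = FALSE]
    }
    n <- nrow(sites)
    sites$modified <- FALSE
    sites$modified[sample(n, max(1L, round(config$prop_modified * n)))] <- TRUE
    sites$stoichiometry <- if (length(config$stoichiometry) == 2L) {
      runif(n, config$stoichiometry[1], config$stoichiometry[2])
    } else rep(config$stoichiometry, n)
    sites$stoichiometry[!sites$modified] <- 0
    sites$depth <- sample(config$reads_per_site[1]:config$reads_per_site[2],
                          n, replace = TRUE)

    events <- list(); read_labels <- numeric(0)
    shift <- config$signal_shift_sd * config$signal_sd
    for (i in seq_len(n)) {
      key <- paste0(sites$transcript_id[i], ":", sites$center_pos[i])
      tx_seq <- seqs[[sites$transcript_id[i]]]
      center <- sites$center_pos[i]
      kmer_chars <- strsplit(sites$kmer[i], "")[[1]]
      # per-position pore means from the 5-mer centered at each base
      base_means <- vapply(-2:2, function(off) {
        pos <- center + off           # 0-based
        lo <- max(1L, pos - 1L); hi <- min(nchar(tx_seq), pos + 3L)
        pore_mean(substr(tx_seq, lo, hi))
      }, numeric(1))

      depth <- sites$depth[i]
      mod <- rep(0, depth)
      if (sites$modified[i]) {
        mod <- rbinom(depth, 1L, sites$stoichiometry[i])
        if (sum(mod) == 0L) mod[sample(depth, 1L)] <- 1L
      }
      site_events <- vector("list", depth)
      for (r in seq_len(depth)) {
        rid <- sprintf("%s#rd%03d", key, r)
        samples <- vector("list", 5L)
        calls <- data.frame(called_base = kmer_chars, qual = 0,
                            ins = 0, del = 0, stringsAsFactors = FALSE)
        for (pidx in seq_len(5L)) {
          mu <- base_means[pidx]
          qual_mu <- 30; mismatch_p <- 0.01
          if (mod[r] == 1L && pidx == 3L) {
            mu <- mu + shift
            mismatch_p <- mismatch_p + config$error_inflation
            qual_mu <- qual_mu - 10 * config$error_inflation
          }
          if (runif(1) < 0.01) {          # deletion
            calls$called_base[pidx] <- "."
            calls$del[pidx] <- 1
            samples[[pidx]] <- numeric(0)
            next
          }
          ndw <- 1L + rgeom(1L, 1 / config$dwell_mean)
          samples[[pidx]] <- rnorm(ndw, mu, config$signal_sd)
          if (runif(1) < mismatch_p) {
            calls$called_base[pidx] <-
              sample(setdiff(c("A", "C", "G", "T"), kmer_chars[pidx]), 1L)
          }
          calls$qual[pidx] <- max(1, min(40, round(rnorm(1, qual_mu, 3))))
          if (runif(1) < 0.02) calls$ins[pidx] <- 1
        }
        if (all(calls$del == 1)) {        # keep at least the center base
          calls$del[3] <- 0
          calls$called_base[3] <- kmer_chars[3]
          calls$qual[3] <- 30
          samples[[3]] <- rnorm(1L, base_means[3], config$signal_sd)
        }
        site_events[[r]] <- read_site_events(rid, samples, calls)
        read_labels[rid] <- mod[r]
      }
      events[[key]] <- site_events
    }
    structure(
      list(sequences = seqs, sites = sites, events = events,
           read_labels = read_labels, config = config),
      class = "m6a_dataset"
    )
  })
}

#' @export
print.m6a_dataset <- function(x, ...) {
  cat(sprintf(
    "m6a_dataset: %d transcripts, %d sites (%d modified), %d reads\n",
    length(x$sequences), nrow(x$sites), sum(x$sites$modified),
    length(x$read_labels)))
  invisible(x)
}

#' Assemble site bags directly from an in-memory synthetic dataset
#'
#' @param dataset An [gen_m6a_dataset()] result.
#' @param min_reads Coverage threshold.
#' @return As [build_site_bags()]; instances carry the designed read labels,
#'   bags their OR.
#' @export
m6a_bags <- function(dataset, min_reads = 3L) {
  build_site_bags(dataset$sites, dataset$events, min_reads,
                  read_labels = dataset$read_labels)
}

#' Write a synthetic m6A dataset to disk in the standard dialects
#'
#' Emits `ref.fa` (FASTA reference), `eventalign.tsv` (signal dialect),
#' `sam2tsv.tsv` (alignment dialect), `truth_sites.tsv`, `truth_reads.tsv`
#' and `manifest.json` (seed and config echo).
#'
#' @param dataset An [gen_m6a_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_m6a_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "ref.fa"),
             eventalign = file.path(dir, "eventalign.tsv"),
             sam2tsv = file.path(dir, "sam2tsv.tsv"),
             truth_sites = file.path(dir, "truth_sites.tsv"),
             truth_reads = file.path(dir, "truth_reads.tsv"),
             manifest = file.path(dir, "manifest.json"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(dataset$sequences), paths["fasta"])

  ev_rows <- list(); al_rows <- list()
  for (key in names(dataset$events)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    tx <- parts[1]; center <- as.integer(parts[2])
    site <- dataset$sites[dataset$sites$transcript_id == tx &
                            dataset$sites$center_pos == center, ]
    ref_chars <- strsplit(site$kmer[1], "")[[1]]
    for (ev in dataset$events[[key]]) {
      for (pidx in seq_len(5L)) {
        pos <- center + pidx - 3L
        if (length(ev$samples[[pidx]]) > 0L) {
          ev_rows[[length(ev_rows) + 1L]] <- data.frame(
            contig = tx, position = pos,
            reference_kmer = site$kmer[1], read_name = ev$read_id,
            samples = paste(sprintf("%.6g", ev$samples[[pidx]]),
                            collapse = ","),
            stringsAsFactors = FALSE)
        }
        cl <- ev$calls[pidx, ]
        op <- if (cl$del == 1) "D" else if (cl$called_base ==
                                              ref_chars[pidx]) "M" else "X"
        al_rows[[length(al_rows) + 1L]] <- data.frame(
          read_name = ev$read_id, contig = tx, ref_pos = pos,
          read_base = cl$called_base, ref_base = ref_chars[pidx],
          base_qual = cl$qual, cigar_op = op, stringsAsFactors = FALSE)
        if (cl$ins == 1) {
          al_rows[[length(al_rows) + 1L]] <- data.frame(
            read_name = ev$read_id, contig = tx, ref_pos = pos,
            read_base = "N", ref_base = ".", base_qual = 10,
            cigar_op = "I", stringsAsFactors = FALSE)
        }
      }
    }
  }
  write.table(do.call(rbind, ev_rows), paths["eventalign"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, al_rows), paths["sam2tsv"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$sites, paths["truth_sites"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(read_id = names(dataset$read_labels),
               label = as.integer(dataset$read_labels)),
    paths["truth_reads"], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$config; class(cfg) <- NULL
  writeLines(jsonlite::toJSON(list(seed = dataset$config$seed, config = cfg),
                              auto_unbox = TRUE, null = "null", digits = NA),
             paths["manifest"])
  invisible(paths)
}
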