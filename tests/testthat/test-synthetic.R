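test_that("generic MIL bags satisfy the OR assumption by construction", {
  bags <- gen_mil_bags(mil_gen_config(n_bags = 40, seed = 3))
  for (b in bags) {
    inst_labels <- vapply(b$instances, function(i) i$hidden_label, numeric(1))
    expect_equal(b$hidden_bag_label, as.numeric(any(inst_labels == 1)))
  }
  # positive bags contain at least one positive instance even at tiny rates
  bags_lo <- gen_mil_bags(mil_gen_config(n_bags = 40,
                                         positive_instance_rate = 0.01,
                                         seed = 4))
  pos <- Filter(function(b) b$hidden_bag_label == 1, bags_lo)
  expect_true(all(vapply(pos, function(b) {
    any(vapply(b$instances, function(i) i$hidden_label, numeric(1)) == 1)
  }, logical(1))))
  expect_error(mil_gen_config(positive_instance_rate = 0),
               "at least one positive instance")
})

test_that("generic MIL generation is deterministic under a fixed seed", {
  b1 <- gen_mil_bags(mil_gen_config(n_bags = 20, seed = 17))
  b2 <- gen_mil_bags(mil_gen_config(n_bags = 20, seed = 17))
  expect_identical(b1, b2)
  b3 <- gen_mil_bags(mil_gen_config(n_bags = 20, seed = 18))
  expect_false(identical(b1, b3))
})

test_that("zero separation makes MIL instance populations indistinguishable", {
  pvals <- vapply(1:10, function(s) {
    bags <- gen_mil_bags(mil_gen_config(n_bags = 60, class_separation = 0,
                                        seed = s))
    feats <- lapply(bags, function(b) {
      vapply(b$instances, function(i) i$features[1], numeric(1))
    })
    labs <- lapply(bags, function(b) {
      vapply(b$instances, function(i) i$hidden_label, numeric(1))
    })
    x <- unlist(feats); y <- unlist(labs)
    suppressWarnings(ks.test(x[y == 1], x[y == 0])$p.value)
  }, numeric(1))
  expect_gt(max(pvals), 0.01)
  expect_gt(mean(pvals > 0.01), 0.8)
})

test_that("m6A generator honors stoichiometry and determinism", {
  cfg <- m6a_gen_config(n_transcripts = 5L, transcript_length = 150L,
                        stoichiometry = 1.0, seed = 9L)
  ds <- gen_m6a_dataset(cfg)
  mod_sites <- ds$sites[ds$sites$modified, ]
  for (i in seq_len(nrow(mod_sites))) {
    key <- paste0(mod_sites$transcript_id[i], ":", mod_sites$center_pos[i])
    labs <- ds$read_labels[vapply(ds$events[[key]],
                                  function(e) e$read_id, character(1))]
    expect_true(all(labs == 1))
  }
  unmod <- ds$sites[!ds$sites$modified, ]
  expect_true(all(unmod$stoichiometry == 0))

  ds2 <- gen_m6a_dataset(cfg)
  expect_identical(ds$sequences, ds2$sequences)
  expect_identical(ds$read_labels, ds2$read_labels)
})

test_that("null m6A data leaves modified and unmodified reads exchangeable", {
  pvals <- vapply(1:10, function(s) {
    cfg <- m6a_gen_config(n_transcripts = 8L, transcript_length = 200L,
                          signal_shift_sd = 0, error_inflation = 0,
                          seed = 100L + s)
    ds <- gen_m6a_dataset(cfg)
    bb <- m6a_bags(ds, min_reads = 3L)
    center_mean <- unlist(lapply(bb$bags, function(b) {
      X <- vapply(b$instances, function(i) i$features[11], numeric(1))
      X - median(X)    # remove kmer baseline before pooling across sites
    }))
    y <- unlist(lapply(bb$bags, function(b) {
      vapply(b$instances, function(i) i$hidden_label, numeric(1))
    }))
    suppressWarnings(ks.test(center_mean[y == 1], center_mean[y == 0])$p.value)
  }, numeric(1))
  expect_gt(mean(pvals > 0.01), 0.8)
})

test_that("configured signal shift is recovered empirically at high depth", {
  cfg <- m6a_gen_config(n_transcripts = 10L, transcript_length = 200L,
                        n_sites = 10L, prop_modified = 1.0,
                        stoichiometry = 0.5, reads_per_site = c(250L, 250L),
                        signal_shift_sd = 2, error_inflation = 0,
                        seed = 77L)
  ds <- gen_m6a_dataset(cfg)
  bb <- m6a_bags(ds, min_reads = 3L)
  shifts <- vapply(bb$bags, function(b) {
    mu <- vapply(b$instances, function(i) i$features[11], numeric(1))
    y <- vapply(b$instances, function(i) i$hidden_label, numeric(1))
    (mean(mu[y == 1]) - mean(mu[y == 0])) / cfg$signal_sd
  }, numeric(1))
  expect_equal(mean(shifts), 2, tolerance = 0.1)
})

test_that("generated feature tables flow through ingestion at 40 features", {
  cfg <- m6a_gen_config(n_transcripts = 3L, transcript_length = 120L,
                        reads_per_site = c(3L, 6L), seed = 33L)
  ds <- gen_m6a_dataset(cfg)
  bb <- m6a_bags(ds, min_reads = 3L)
  expect_gt(length(bb$bags), 0L)
  dims <- unlist(lapply(bb$bags, function(b) {
    vapply(b$instances, function(i) length(i$features), integer(1))
  }))
  expect_true(all(dims == 40L))
})
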