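test_that("RRACH scanning finds centered, overlapping motifs", {
  s1 <- scan_rrach("TTGGACTTT", "tx")
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$center_pos, 4L)
  expect_equal(s1$kmer, "GGACT")
  expect_equal(nrow(scan_rrach("AAAAA")), 0L)
  s2 <- scan_rrach("GGACAGGACT", "tx")
  expect_equal(s2$center_pos, c(2L, 7L))
  expect_equal(s2$kmer, c("GGACA", "GGACT"))
  # U is normalized to T; case is ignored
  expect_equal(scan_rrach("uuggacuuu")$center_pos, 4L)
  expect_error(scan_rrach("GGAXC"), "non-IUPAC")
})

test_that("RRACH scanning agrees with a regex oracle on random sequences", {
  set.seed(123)
  for (i in seq_len(1000)) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
    got <- scan_rrach(s)$center_pos
    m <- gregexpr("(?=([AG][AG]AC[ACT]))", s, perl = TRUE)[[1]]
    want <- if (m[1] == -1L) integer(0) else as.integer(m) + 1L
    expect_identical(got, want)
  }
})

test_that("signal features are per-position robust statistics", {
  ev <- make_events(samples = list(c(1, 2, 3, 4), 5, c(1, 1), c(2, 2), 7))
  f <- signal_features(ev)
  expect_length(f, 20L)
  expect_equal(f[1:4], c(2.5, 1.118034, 2.5, 4), tolerance = 1e-6)
  expect_equal(f[5:8], c(5, 0, 5, 1))
  # deleted base emits the sentinel block
  ev_del <- make_events(samples = list(c(1, 2), numeric(0), c(1, 2), c(1, 2),
                                       c(1, 2)),
                        del = c(0, 1, 0, 0, 0))
  fd <- signal_features(ev_del)
  expect_equal(fd[5:8], c(0, 0, 0, 0))
})

test_that("alignment features flag mismatch, insertion and deletion", {
  ev <- make_events()
  f <- alignment_features(ev, "GGACT")
  expect_length(f, 20L)
  expect_equal(f, rep(c(30, 0, 0, 0), 5))
  # mismatch at offset +1 only
  ev_mm <- make_events(bases = c("G", "G", "A", "T", "T"))
  mm <- alignment_features(ev_mm, "GGACT")
  expect_equal(mm[seq(2, 20, 4)], c(0, 0, 0, 1, 0))
  # deleted center base
  ev_del <- make_events(samples = list(c(1), c(1), numeric(0), c(1), c(1)),
                        del = c(0, 0, 1, 0, 0))
  dd <- alignment_features(ev_del, "GGACT")
  expect_equal(dd[9:12], c(0, 0, 0, 1))
  expect_equal(signal_features(ev_del)[9:12], c(0, 0, 0, 0))
})

test_that("site bags respect the coverage filter and 40-feature schema", {
  sites <- data.frame(transcript_id = "tx", center_pos = c(4L, 10L),
                      kmer = c("GGACT", "AGACA"), stringsAsFactors = FALSE)
  evs4 <- lapply(1:4, function(i) make_events(sprintf("r%d", i)))
  evs6 <- lapply(1:6, function(i) make_events(sprintf("q%d", i)))
  per_site <- list("tx:4" = evs4, "tx:10" = evs6)

  b3 <- build_site_bags(sites, per_site, min_reads = 3)
  expect_equal(b3$report$n_kept, 2L)
  b5 <- build_site_bags(sites, per_site, min_reads = 5)
  expect_equal(b5$report$n_kept, 1L)
  expect_equal(b5$report$n_dropped, 1L)
  expect_equal(b5$bags[[1]]$bag_id, "tx:10")
  b20 <- build_site_bags(sites, per_site, min_reads = 20)
  expect_equal(length(b20$bags), 0L)

  # monotone nesting of kept site sets
  ids <- function(x) vapply(x$bags, function(b) b$bag_id, character(1))
  expect_true(all(ids(b20) %in% ids(b5)))
  expect_true(all(ids(b5) %in% ids(b3)))

  for (b in b3$bags) {
    for (inst in b$instances) expect_length(inst$features, 40L)
  }

  empty <- build_site_bags(sites[0, ], list(), min_reads = 3)
  expect_equal(empty$report, list(n_kept = 0L, n_dropped = 0L))
})

test_that("feature extraction is per-read: permuting reads permutes values", {
  sites <- data.frame(transcript_id = "tx", center_pos = 4L, kmer = "GGACT",
                      stringsAsFactors = FALSE)
  evs <- lapply(1:5, function(i) {
    make_events(sprintf("r%d", i),
                samples = rep(list(rnorm(4) + i), 5))
  })
  a <- build_site_bags(sites, list("tx:4" = evs), 3)$bags[[1]]
  b <- build_site_bags(sites, list("tx:4" = rev(evs)), 3)$bags[[1]]
  fa <- lapply(a$instances, function(i) i$features)
  fb <- rev(lapply(b$instances, function(i) i$features))
  expect_equal(fa, fb)
})

test_that("eventalign rows for the same base are grouped and concatenated", {
  sites <- data.frame(transcript_id = "tx", center_pos = 4L, kmer = "GGACT",
                      stringsAsFactors = FALSE)
  tab <- data.frame(
    contig = "tx",
    position = c(2L, 3L, 4L, 4L, 5L, 6L),
    reference_kmer = "GGACT",
    read_name = "r1",
    samples = c("1,2", "3", "4,5", "6", "7,8", "9"),
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- read_eventalign(path, sites)
  expect_named(sig, "tx:4")
  slots <- sig[["tx:4"]][["r1"]]
  expect_equal(slots[[3]], c(4, 5, 6))   # split event rows concatenated
  expect_equal(slots[[1]], c(1, 2))
  expect_equal(slots[[5]], 9)
})

test_that("synthetic datasets survive the on-disk dialect round trip", {
  cfg <- m6a_gen_config(n_transcripts = 4L, transcript_length = 120L,
                        prop_modified = 0.5, reads_per_site = c(4L, 8L),
                        seed = 21L)
  ds <- gen_m6a_dataset(cfg)
  dir <- tempfile()
  paths <- write_m6a_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  res <- featurize_m6a(paths["fasta"], paths["eventalign"], paths["sam2tsv"],
                       min_reads = 3L, read_labels = ds$read_labels)
  # every designed site with enough coverage is recovered with its depth
  direct <- m6a_bags(ds, min_reads = 3L)
  expect_setequal(vapply(res$bags, function(b) b$bag_id, character(1)),
                  vapply(direct$bags, function(b) b$bag_id, character(1)))
  for (b in res$bags) {
    d <- direct$bags[[which(vapply(direct$bags, function(x) x$bag_id,
                                   character(1)) == b$bag_id)]]
    expect_equal(length(b$instances), length(d$instances))
    expect_equal(b$hidden_bag_label, d$hidden_bag_label)
    for (inst in b$instances) expect_length(inst$features, 40L)
  }
})

test_that("prediction writer emits TSV and BED6 in transcript coordinates", {
  sites <- data.frame(transcript_id = "tx1", center_pos = 7L, kmer = "GGACT",
                      stringsAsFactors = FALSE)
  preds <- data.frame(bag_id = "tx1:7", n_reads = 12L, site_prob = 0.85,
                      cls_prob = 0.7, stringsAsFactors = FALSE)
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_predictions(preds, sites, tsv, bed)
  out <- read.delim(tsv)
  expect_equal(out$center_pos, 7L)
  expect_equal(out$site_prob, 0.85)
  bed_out <- read.delim(bed, header = FALSE)
  expect_equal(bed_out$V2, 7L)
  expect_equal(bed_out$V3, 8L)
  expect_equal(bed_out$V5, 850)
  expect_equal(bed_out$V6, "+")
})
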