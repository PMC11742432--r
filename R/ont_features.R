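# m6A front end: RRACH motif scanning over transcript references and
# per-read 40-feature extraction. Each candidate site contributes one bag;
# each covering read contributes one instance whose features are, for the
# five motif positions (-2..+2 around the central A): median, population SD,
# mean and count of the raw signal samples (20 values), followed by per-base
# quality, mismatch, insertion and deletion indicators (20 values).

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Scan a transcript for RRACH motifs
#'
#' Finds every 5-mer window matching R R A C H (R in \{A, G\}, H in
#' \{A, C, T\}) and reports a candidate site centered on the A (0-based
#' transcript coordinate, window start + 2). Overlapping windows are all
#' reported. `U` is normalized to `T` at ingest.
#'
#' @param sequence Transcript sequence (IUPAC DNA/RNA string, any case).
#' @param transcript_id Identifier copied into the output.
#' @return A data frame with columns `transcript_id`, `center_pos` (0-based)
#'   and `kmer`; zero rows when the motif is absent.
#' @export
scan_rrach <- function(sequence, transcript_id = "tx") {
  s <- chartr("u", "U", toupper(sequence))
  s <- gsub("U", "T", s, fixed = TRUE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% IUPAC_CHARS)
  if (length(bad)) {
    stop("non-IUPAC character '", chars[bad[1]], "' at position ",
         bad[1] - 1L, " of ", transcript_id)
  }
  # lookahead so overlapping motifs are all found
  m <- gregexpr("(?=[AG][AG]AC[ACT])", s, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(transcript_id = character(0),
                      center_pos = integer(0), kmer = character(0)))
  }
  starts <- as.integer(m)
  data.frame(
    transcript_id = transcript_id,
    center_pos = starts + 1L,             # 0-based center = (start-1) + 2
    kmer = substring(s, starts, starts + 4L),
    stringsAsFactors = FALSE
  )
}

#' Scan all transcripts of a FASTA file for RRACH motifs
#'
#' @param fasta_path Path to a (possibly multi-record) FASTA file.
#' @return A data frame as in [scan_rrach()], rows over all transcripts.
#' @export
scan_rrach_fasta <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    scan_rrach(as.character(seqs[[i]]), names(seqs)[i])
  })
  do.call(rbind, out)
}

#' Per-read event record at one site
#'
#' Holds the raw inputs to the feature computations for one read over the
#' five motif positions: per-base raw-signal sample lists and per-base call
#' records.
#'
#' @param read_id Read identifier.
#' @param samples List of 5 numeric vectors of raw signal samples
#'   (offsets -2..+2); a vector may be empty only when that base is deleted.
#' @param calls Data frame with 5 rows and columns `called_base`, `qual`
#'   (phred), `ins` (insertion adjacent to this base, 0/1), `del` (base
#'   deleted in the read, 0/1).
#' @return An object of class `read_site_events`.
#' @export
read_site_events <- function(read_id, samples, calls) {
  stopifnot(length(samples) == 5L, nrow(calls) == 5L)
  empty_ok <- vapply(seq_len(5L), function(i) {
    length(samples[[i]]) > 0L || calls$del[i] == 1
  }, logical(1))
  if (!all(empty_ok)) {
    stop("read '", read_id, "': empty sample list at a non-deleted base")
  }
  structure(list(read_id = read_id, samples = samples, calls = calls),
            class = "read_site_events")
}

#' Signal features for one read at one site
#'
#' Per motif position: median, population standard deviation, mean and count
#' of the raw signal samples. A deleted base emits the sentinel (0, 0, 0, 0).
#'
#' @param events A [read_site_events()].
#' @return Numeric vector of length 20, positions -2..+2 blocked as
#'   (median, sd, mean, count).
#' @export
signal_features <- function(events) {
  if (all(vapply(events$samples, length, 1L) == 0L)) {
    stop("read '", events$read_id, "': no signal samples at any position")
  }
  out <- lapply(seq_len(5L), function(i) {
    x <- events$samples[[i]]
    if (length(x) == 0L) return(c(0, 0, 0, 0))
    mu <- mean(x)
    c(median(x), sqrt(mean((x - mu)^2)), mu, length(x))
  })
  unlist(out, use.names = FALSE)
}

#' Base-alignment features for one read at one site
#'
#' Per motif position: phred quality (0 when deleted), mismatch indicator
#' (called base differs from the reference base), insertion indicator
#' (insertion adjacent to the base in this read) and deletion indicator.
#' Computed per read, so the "frequencies" are 0/1 indicators; across-read
#' frequencies at a site are recoverable by averaging over the bag.
#'
#' @param events A [read_site_events()].
#' @param kmer The site's 5-mer reference context.
#' @return Numeric vector of length 20, positions -2..+2 blocked as
#'   (quality, mismatch, insertion, deletion).
#' @export
alignment_features <- function(events, kmer) {
  ref <- strsplit(toupper(kmer), "", fixed = TRUE)[[1]]
  stopifnot(length(ref) == 5L)
  out <- lapply(seq_len(5L), function(i) {
    cl <- events$calls[i, ]
    if (cl$del == 1) return(c(0, 0, 0, 1))
    c(cl$qual, as.numeric(toupper(cl$called_base) != ref[i]),
      as.numeric(cl$ins), 0)
  })
  unlist(out, use.names = FALSE)
}

#' Assemble site bags from per-read events
#'
#' One bag per candidate site with at least `min_reads` covering reads; each
#' instance is the 40-vector `signal_features || alignment_features`. Sites
#' below the coverage threshold are dropped and counted.
#'
#' @param sites Data frame from [scan_rrach()] / [scan_rrach_fasta()].
#' @param per_read_events Named list keyed `"transcript:center_pos"`; each
#'   element a list of [read_site_events()] covering that site.
#' @param min_reads Coverage threshold (>= 1); the benchmarking protocol uses
#'   3, 5 and 20.
#' @param read_labels Optional named 0/1 vector keyed by read id (synthetic
#'   truth); instances pick up hidden labels, bags their OR.
#' @return A list with `bags` (list of [site_bag()]), `sites` (the kept
#'   subset of `sites` with an `n_reads` column) and `report`
#'   (`n_kept`, `n_dropped`).
#' @export
build_site_bags <- function(sites, per_read_events, min_reads = 3L,
                            read_labels = NULL) {
  stopifnot(min_reads >= 1L)
  bags <- list(); kept <- integer(0)
  if (nrow(sites) > 0) {
    for (i in seq_len(nrow(sites))) {
      key <- paste0(sites$transcript_id[i], ":", sites$center_pos[i])
      evs <- per_read_events[[key]]
      if (is.null(evs) || length(evs) < min_reads) next
      inst <- lapply(evs, function(ev) {
        lab <- NA
        if (!is.null(read_labels) && ev$read_id %in% names(read_labels)) {
          lab <- read_labels[[ev$read_id]]
        }
        instance_feature(
          ev$read_id,
          c(signal_features(ev), alignment_features(ev, sites$kmer[i])),
          hidden_label = lab)
      })
      bags[[key]] <- site_bag(key, inst)
      kept <- c(kept, i)
    }
  }
  kept_sites <- sites[kept, , drop = FALSE]
  if (length(kept)) {
    kept_sites$n_reads <- vapply(bags, function(b) length(b$instances), 1L)
  }
  list(bags = unname(bags), sites = kept_sites,
       report = list(n_kept = length(kept),
                     n_dropped = nrow(sites) - length(kept)))
}

# -- event-table dialects -----------------------------------------------------

#' Read an eventalign-like signal table
#'
#' Tab-delimited with header; columns `contig`, `position` (0-based reference
#' position of the base), `reference_kmer`, `read_name`, `samples`
#' (comma-separated raw signal values for one event). Multiple event rows for
#' the same read/base are concatenated, as resquiggled events may be split.
#'
#' @param path TSV path.
#' @param sites Data frame of candidate sites (from [scan_rrach_fasta()]).
#' @return Nested list: `[["transcript:center_pos"]][[read_id]]` ->
#'   list of 5 numeric sample vectors (offsets -2..+2).
#' @export
read_eventalign <- function(path, sites) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  need <- c("contig", "position", "read_name", "samples")
  if (!all(need %in% names(tab))) {
    stop("eventalign table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(sites))) {
    key <- paste0(sites$transcript_id[i], ":", sites$center_pos[i])
    center <- sites$center_pos[i]
    sub <- tab[tab$contig == sites$transcript_id[i] &
                 tab$position >= center - 2L & tab$position <= center + 2L, ,
               drop = FALSE]
    if (nrow(sub) == 0L) next
    site_map <- list()
    for (r in unique(sub$read_name)) {
      rows <- sub[sub$read_name == r, , drop = FALSE]
      slots <- rep(list(numeric(0)), 5L)
      for (j in seq_len(nrow(rows))) {
        off <- rows$position[j] - center + 3L   # 1..5
        vals <- as.numeric(strsplit(rows$samples[j], ",", fixed = TRUE)[[1]])
        slots[[off]] <- c(slots[[off]], vals)
      }
      site_map[[r]] <- slots
    }
    out[[key]] <- site_map
  }
  out
}

#' Read a sam2tsv-like per-base alignment table
#'
#' Tab-delimited with header; one row per read base with columns `read_name`,
#' `contig`, `ref_pos` (0-based), `read_base`, `ref_base`, `base_qual`
#' (phred integer) and `cigar_op` (`M`, `X`, `=`, `I`, `D`). Insertion rows
#' (`I`) carry the reference position of the adjacent base and flag it;
#' deletion rows (`D`) have `read_base` "." and quality 0.
#'
#' @param path TSV path.
#' @param sites Candidate site table.
#' @return Nested list: `[["transcript:center_pos"]][[read_id]]` -> a
#'   5-row call data frame (`called_base`, `qual`, `ins`, `del`).
#' @export
read_sam2tsv <- function(path, sites) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  need <- c("read_name", "contig", "ref_pos", "read_base", "base_qual",
            "cigar_op")
  if (!all(need %in% names(tab))) {
    stop("sam2tsv table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(sites))) {
    key <- paste0(sites$transcript_id[i], ":", sites$center_pos[i])
    center <- sites$center_pos[i]
    sub <- tab[tab$contig == sites$transcript_id[i] &
                 tab$ref_pos >= center - 2L & tab$ref_pos <= center + 2L, ,
               drop = FALSE]
    if (nrow(sub) == 0L) next
    site_map <- list()
    for (r in unique(sub$read_name)) {
      rows <- sub[sub$read_name == r, , drop = FALSE]
      calls <- data.frame(called_base = rep(NA_character_, 5L),
                          qual = rep(0, 5L), ins = rep(0, 5L),
                          del = rep(0, 5L), stringsAsFactors = FALSE)
      for (j in seq_len(nrow(rows))) {
        off <- rows$ref_pos[j] - center + 3L
        op <- rows$cigar_op[j]
        if (op == "I") {
          calls$ins[off] <- 1
        } else if (op == "D") {
          calls$called_base[off] <- "."
          calls$del[off] <- 1
          calls$qual[off] <- 0
        } else {
          calls$called_base[off] <- rows$read_base[j]
          calls$qual[off] <- rows$base_qual[j]
        }
      }
      # positions never reported for this read are treated as deleted
      miss <- is.na(calls$called_base) & calls$del == 0
      calls$called_base[miss] <- "."
      calls$del[miss] <- 1
      site_map[[r]] <- calls
    }
    out[[key]] <- site_map
  }
  out
}

#' Build site bags from reference FASTA plus event tables
#'
#' Joins the signal dialect (eventalign-like) and the alignment dialect
#' (sam2tsv-like) per read and site, then assembles 40-feature bags. A read
#' contributes only if it appears in both tables at the site.
#'
#' @param fasta_path Transcript reference FASTA.
#' @param eventalign_path Signal table (see [read_eventalign()]).
#' @param sam2tsv_path Alignment table (see [read_sam2tsv()]).
#' @param min_reads Coverage threshold.
#' @param read_labels Optional named 0/1 truth vector by read id.
#' @return As [build_site_bags()].
#' @export
featurize_m6a <- function(fasta_path, eventalign_path, sam2tsv_path,
                          min_reads = 3L, read_labels = NULL) {
  sites <- scan_rrach_fasta(fasta_path)
  if (is.null(sites) || nrow(sites) == 0L) {
    return(list(bags = list(),
                sites = data.frame(transcript_id = character(0),
                                   center_pos = integer(0),
                                   kmer = character(0)),
                report = list(n_kept = 0L, n_dropped = 0L)))
  }
  sig <- read_eventalign(eventalign_path, sites)
  aln <- read_sam2tsv(sam2tsv_path, sites)
  events <- list()
  for (key in intersect(names(sig), names(aln))) {
    reads <- intersect(names(sig[[key]]), names(aln[[key]]))
    events[[key]] <- lapply(reads, function(r) {
      read_site_events(r, sig[[key]][[r]], aln[[key]][[r]])
    })
  }
  build_site_bags(sites, events, min_reads, read_labels)
}

# -- prediction output --------------------------------------------------------

#' Write site predictions as TSV (and optionally BED6)
#'
#' The TSV has columns `transcript_id`, `center_pos` (0-based), `kmer`,
#' `n_reads`, `site_prob`. The optional BED6 uses the half-open interval
#' `[center_pos, center_pos + 1)`, score `round(1000 * site_prob)` and
#' strand `"+"`.
#'
#' @param predictions `sites` data frame from [predict_bags()] whose bag ids
#'   have the form `"transcript:center_pos"`.
#' @param site_info Site table carrying `transcript_id`, `center_pos`,
#'   `kmer` (from the featurizer).
#' @param tsv_path Output TSV path.
#' @param bed_path Optional BED6 output path.
#' @return Invisibly, the TSV path.
#' @export
write_predictions <- function(predictions, site_info, tsv_path,
                              bed_path = NULL) {
  keys <- paste0(site_info$transcript_id, ":", site_info$center_pos)
  m <- match(predictions$bag_id, keys)
  out <- data.frame(
    transcript_id = site_info$transcript_id[m],
    center_pos = site_info$center_pos[m],
    kmer = site_info$kmer[m],
    n_reads = predictions$n_reads,
    site_prob = predictions$site_prob,
    stringsAsFactors = FALSE
  )
  write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(out$transcript_id, out$center_pos, out$center_pos + 1L,
                      paste0(out$transcript_id, ":", out$center_pos),
                      round(1000 * out$site_prob), "+")
    write.table(bed, bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(tsv_path)
}
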