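# Tumour genome simulation: somatic L1-mediated insertions applied to an
# individual's germline (which first materialises any carried non-reference
# donor elements at their insertion points).

# Sample one somatic insert from a donor. Mechanism, 5'->3' of the mobilised
# transcript: [optionally inverted 5' prefix][retained donor 3' end]
# [transduced 3' flank up to a polyA addition site][polyA tail]; reverse
# transcription is often incomplete, so the retained donor length is
# geometric with heavy mass near zero.
build_insert <- function(dl, config) {
  elem <- dl$element
  elen <- nchar(elem)
  transduce <- (stats::runif(1) < config$p_transduction) &&
    length(dl$polya_site_offsets) > 0
  s <- if (transduce) sample(dl$polya_site_offsets, 1L) else 0L
  t_len <- min(stats::rgeom(1L, 1 / (config$truncation_mean + 1)), elen)
  donor_part <- if (t_len > 0) substr(elem, elen - t_len + 1L, elen) else ""
  trans_part <- if (s > 0) substr(dl$flank, 1L, s) else ""
  body <- paste0(donor_part, trans_part)

  inv_len <- NA_integer_; inv_gap <- NA_integer_
  if (stats::runif(1) < config$p_inversion &&
      nchar(body) >= config$inversion_len_range[1] +
        config$inversion_gap_range[1] + 20L) {
    max_l <- min(config$inversion_len_range[2], (nchar(body) - 20L) %/% 2L)
    if (max_l >= config$inversion_len_range[1]) {
      inv_len <- sample(seq(config$inversion_len_range[1], max_l), 1L)
      max_g <- min(config$inversion_gap_range[2],
                   nchar(body) - 2L * inv_len - 10L)
      if (max_g >= config$inversion_gap_range[1]) {
        inv_gap <- sample(seq(config$inversion_gap_range[1], max_g), 1L)
        body <- paste0(revcomp(substr(body, 1L, inv_len)),
                       substr(body, inv_len + inv_gap + 1L, nchar(body)))
      } else inv_len <- NA_integer_
    }
  }

  tail_len <- sample(seq(config$polya_tail_range[1],
                         config$polya_tail_range[2]), 1L)
  seq5to3 <- paste0(body, strrep("A", tail_len))
  orientation <- sample(c("+", "-"), 1L)
  list(seq = if (orientation == "+") seq5to3 else revcomp(seq5to3),
       donor = dl$id, retained3p = as.integer(t_len),
       transduced = as.integer(s),
       polya_site = if (s > 0) {
         i <- match(s, dl$polya_site_offsets)
         if (dl$strand == "+") dl$flank_start - 1L + s else dl$flank_end + 1L - s
       } else NA_integer_,
       tail_len = as.integer(tail_len), inv_len = inv_len, inv_gap = inv_gap,
       orientation = orientation, insert_len = nchar(seq5to3))
}

# Apply insertions (1-based target pos p, tsd t) to one chromosome string.
# t >= 1 duplicates ref[p..p+t-1] on both sides of the insert; t == 0 is a
# clean insertion before p; t < 0 deletes -t target bases.
apply_insertions <- function(seq, pos, tsd, insert_seq) {
  if (length(pos) == 0L) return(seq)
  o <- order(pos)
  pos <- pos[o]; tsd <- tsd[o]; insert_seq <- insert_seq[o]
  parts <- character(0)
  cur <- 1L
  for (i in seq_along(pos)) {
    p <- pos[i]; t <- tsd[i]
    left_end <- if (t > 0) p + t - 1L else p - 1L
    resume <- if (t < 0) p - t else p
    parts <- c(parts, substr(seq, cur, left_end), insert_seq[i])
    cur <- resume
  }
  parts <- c(parts, substr(seq, cur, nchar(seq)))
  paste(parts, collapse = "")
}

# Germline of one individual: reference plus carried non-reference donors
# materialised at their insertion points (element + its polyA tail, with a
# fixed-size target site duplication).
simulate_individual <- function(genome, config, individual_id) {
  set.seed(child_seed(config$seed, "individual", individual_id))
  nonref <- Filter(function(d) !d$in_reference, genome$donors)
  carried <- vapply(nonref, function(d)
    stats::runif(1) < config$p_donor_carrier, logical(1))
  events <- do.call(rbind, lapply(nonref[carried], function(d) {
    data.frame(donor = d$id, chrom = d$chrom, pos = d$insertion_point + 1L,
               tsd = 10L,
               insert_seq = paste0(d$element_seq, strrep("A", d$tail_len)),
               stringsAsFactors = FALSE)
  }))
  seqs <- genome$seqs
  if (!is.null(events)) {
    for (cn in unique(events$chrom)) {
      ev <- events[events$chrom == cn, ]
      seqs[[cn]] <- apply_insertions(seqs[[cn]], ev$pos, ev$tsd, ev$insert_seq)
    }
  }
  list(seqs = seqs, events = events,
       carried = vapply(nonref[carried], `[[`, character(1), "id"))
}

# map reference coordinates to germline coordinates given germline events
ref_to_germline <- function(pos, chrom, events) {
  if (is.null(events)) return(pos)
  shift <- vapply(seq_along(pos), function(i) {
    ev <- events[events$chrom == chrom[i] & events$pos <= pos[i], ]
    if (nrow(ev) == 0) 0L else sum(nchar(ev$insert_seq) + ev$tsd)
  }, integer(1))
  pos + shift
}

#' Simulate one tumour/matched-normal pair
#'
#' Materialises the individual's carried non-reference donors in the
#' germline, then plants somatic L1-mediated insertions: optional 3'
#' transduction up to a sampled polyA addition site, geometric 5' truncation
#' of the donor, optional twin-priming 5' inversion, a 25-60 bp polyA tail
#' and a sampled target-site duplication (or small deletion). Target sites
#' are uniform over positions clear of planted features; placement conflicts
#' are re-sampled with bounded retries.
#'
#' @param genome a `genome_model` from [build_reference()].
#' @param config the [sim_config()].
#' @param tumour_id character or integer label; also seeds this individual's
#'   private random stream.
#' @param n_inserts optional fixed somatic insert count (default: drawn from
#'   the configured negative-binomial law).
#' @return list with `tumour` and `normal` chromosome sequences, the somatic
#'   `truth` table (reference coordinates, 1-based), the germline
#'   `events` of the individual and the `carried` donor ids.
#' @export
simulate_tumour <- function(genome, config, tumour_id, n_inserts = NULL) {
  indiv <- simulate_individual(genome, config, tumour_id)
  set.seed(child_seed(config$seed, "tumour", tumour_id))
  if (is.null(n_inserts)) {
    n_inserts <- stats::rnbinom(1L, mu = config$inserts_per_tumour$mu,
                                size = config$inserts_per_tumour$size)
  }
  dl <- donor_library(genome)
  available <- vapply(dl, function(d) d$in_reference, logical(1)) |
    names(dl) %in% indiv$carried
  dl <- dl[available]

  feats <- feature_intervals(genome)
  margin <- 2000L
  min_sep <- 2000L
  chrom_names <- names(genome$seqs)

  rows <- vector("list", n_inserts)
  chosen <- data.frame(chrom = character(0), pos = integer(0))
  if (n_inserts > 0) for (i in seq_len(n_inserts)) {
    ins <- build_insert(dl[[sample(length(dl), 1L)]], config)
    tsd <- sample(config$tsd_values, 1L, prob = config$tsd_weights)
    ok <- FALSE
    for (try in 1:200) {
      cn <- sample(chrom_names, 1L)
      p <- sample.int(genome$chrom_lengths[[cn]] - 2L * margin, 1L) + margin
      ff <- feats[feats$chrom == cn, , drop = FALSE]
      if (nrow(ff) > 0 && any(p >= ff$start - margin & p <= ff$end + margin))
        next
      prev <- chosen[chosen$chrom == cn, , drop = FALSE]
      if (nrow(prev) > 0 && any(abs(prev$pos - p) < min_sep)) next
      # nick sites are kept off homopolymer steps so that the planted TSD
      # length is the unique longest duplication at the junction
      if (substr(genome$seqs[[cn]], p - 1L, p - 1L) ==
          substr(genome$seqs[[cn]], p, p)) next
      ge <- indiv$events
      if (!is.null(ge)) {
        gg <- ge[ge$chrom == cn, , drop = FALSE]
        if (nrow(gg) > 0 && any(abs(gg$pos - p) < margin)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place somatic insert after bounded retries")
    chosen <- rbind(chosen, data.frame(chrom = cn, pos = p))
    rows[[i]] <- data.frame(
      tumour_id = as.character(tumour_id),
      insert_id = sprintf("%s_ins%03d", tumour_id, i),
      chrom = cn, pos = as.integer(p), donor = ins$donor,
      retained3p = ins$retained3p, transduced = ins$transduced,
      polya_site = ins$polya_site, tail_len = ins$tail_len,
      inv_len = ins$inv_len, inv_gap = ins$inv_gap,
      orientation = ins$orientation, tsd = as.integer(tsd),
      insert_len = ins$insert_len, insert_seq = ins$seq,
      stringsAsFactors = FALSE)
  }
  truth <- if (n_inserts > 0) do.call(rbind, rows) else empty_truth()

  tumour <- indiv$seqs
  if (nrow(truth) > 0) {
    for (cn in unique(truth$chrom)) {
      tt <- truth[truth$chrom == cn, ]
      gpos <- ref_to_germline(tt$pos, tt$chrom, indiv$events)
      tumour[[cn]] <- apply_insertions(tumour[[cn]], gpos, tt$tsd,
                                       tt$insert_seq)
    }
  }
  list(tumour = tumour, normal = indiv$seqs, truth = truth,
       events = indiv$events, carried = indiv$carried)
}

empty_truth <- function() {
  data.frame(tumour_id = character(0), insert_id = character(0),
             chrom = character(0), pos = integer(0), donor = character(0),
             retained3p = integer(0), transduced = integer(0),
             polya_site = integer(0), tail_len = integer(0),
             inv_len = integer(0), inv_gap = integer(0),
             orientation = character(0), tsd = integer(0),
             insert_len = integer(0), insert_seq = character(0),
             stringsAsFactors = FALSE)
}

#' Write and read the somatic-insert truth
#'
#' TSV in 1-based inclusive coordinates (one row per insert, round-trippable
#' via [read_truth()]); BED in 0-based half-open coordinates marking the
#' target interval: the duplicated target bases for `tsd > 0`, a zero-width
#' point for `tsd == 0`, and the deleted target bases for `tsd < 0`.
#'
#' @param truth truth table from [simulate_tumour()].
#' @param tsv,bed output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_truth <- function(truth, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(truth, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
  }
  if (!is.null(bed)) {
    if (nrow(truth) == 0) {
      write_bed(as_bed(character(0), integer(0), integer(0)), bed)
    } else {
      w <- abs(pmin(truth$tsd, 0L)) + pmax(truth$tsd, 0L)  # |tsd|
      end <- ifelse(truth$tsd == 0L, truth$pos - 1L, truth$pos - 1L + w)
      beddf <- data.frame(chrom = truth$chrom, start = truth$pos - 1L,
                          end = end, name = truth$insert_id, score = 0L,
                          strand = truth$orientation,
                          stringsAsFactors = FALSE)
      write_bed(beddf, bed)
    }
  }
  invisible(c(tsv, bed))
}

#' @rdname write_truth
#' @param path TSV path written by `write_truth`.
#' @export
read_truth <- function(path) {
  tr <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (nrow(tr) == 0) return(empty_truth())
  int_cols <- c("pos", "retained3p", "transduced", "polya_site", "tail_len",
                "inv_len", "inv_gap", "tsd", "insert_len")
  for (cc in int_cols) tr[[cc]] <- as.integer(tr[[cc]])
  tr$tumour_id <- as.character(tr$tumour_id)
  tr
}
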