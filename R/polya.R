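# Tumour-specific polyA scan: reads containing a long A/T run anchored by a
# confidently mapped mate locate candidate insertions regardless of whether
# the insert carries any mappable element sequence. T runs are minus-strand
# polyA and are treated symmetrically throughout.

#' Flag reads containing a long polyA/polyT run
#'
#' @param seqs character vector of read sequences.
#' @param min_run run-length threshold (default 20).
#' @return `data.table` with per-read longest A run, longest T run, and the
#'   `flagged` indicator (max of the two at least `min_run`).
#' @export
find_polya_reads <- function(seqs, min_run = 20L) {
  if (length(seqs) == 0L)
    return(data.table::data.table(run_a = integer(0), run_t = integer(0),
                                  run_len = integer(0), flagged = logical(0)))
  runs <- data.table::as.data.table(cpp_longest_runs(seqs))
  runs[, run_len := pmax(run_a, run_t)]
  runs[, flagged := run_len >= min_run]
  runs[]
}

#' Quality filter for scanned reads
#'
#' Reads with `max_lowq_run` or more consecutive minimum-quality bases
#' (symbol `#`) are unusable and discarded.
#'
#' @param seqs,quals read sequences and quality strings (same lengths).
#' @param max_lowq_run threshold (default 80).
#' @param lowq_char the minimum symbol of the encoding scale.
#' @return logical vector: `TRUE` = keep.
#' @export
quality_filter <- function(seqs, quals, max_lowq_run = 80L, lowq_char = "#") {
  if (length(seqs) != length(quals) || any(nchar(seqs) != nchar(quals)))
    stop("malformed records: sequence and quality lengths differ")
  if (length(quals) == 0L) return(logical(0))
  cpp_max_char_run(quals, lowq_char) < max_lowq_run
}

# per-sample anchor records: one row per flagged read whose mate is mapped
# at or above mapq_min. The anchor is the mate placement.
polya_anchors <- function(aln, min_run = 20L, max_lowq_run = 80L,
                          mapq_min = 30L) {
  out <- list()
  for (m in 1:2) {
    o <- 3L - m
    g <- function(col, k) aln[[paste0(col, k)]]
    runs <- find_polya_reads(g("seq", m), min_run)
    keep <- quality_filter(g("seq", m), g("qual", m), max_lowq_run)
    sel <- which(runs$flagged & keep & !is.na(g("chrom", o)) &
                 g("mapq", o) >= mapq_min & !aln$dup)
    if (length(sel) == 0L) next
    out[[m]] <- data.table::data.table(
      qname = aln$qname[sel], read_mate = m,
      run_len = runs$run_len[sel],
      chrom = g("chrom", o)[sel], start = g("pos", o)[sel],
      end = g("pos", o)[sel] + g("alen", o)[sel] - 1L,
      strand = g("strand", o)[sel])
  }
  if (length(out) == 0L)
    return(data.table::data.table(qname = character(0), read_mate = integer(0),
                                  run_len = integer(0), chrom = character(0),
                                  start = integer(0), end = integer(0),
                                  strand = character(0)))
  data.table::rbindlist(Filter(Negate(is.null), out))
}

#' Group anchored polyA reads into candidate insertions
#'
#' Anchors (mate placements of flagged reads) are grouped per chromosome and
#' anchor strand by chaining positions at `cluster_window`; candidates with
#' fewer than `min_support` supporting pairs are flagged, not dropped.
#'
#' @param anchors table from the scan (mate chrom/start/end/strand plus the
#'   flagged read's run length).
#' @param cluster_window linkage window (typically
#'   `fragment_mean + 4*fragment_sd`).
#' @param min_support minimum supporting read pairs (default 3).
#' @param tumour_id label.
#' @return `polya_candidates` table: anchor locus, strand, support, run
#'   lengths, flags.
#' @export
anchor_candidates <- function(anchors, cluster_window, min_support = 3L,
                              tumour_id = NA_character_) {
  empty <- data.table::data.table(
    candidate_id = character(0), tumour_id = character(0),
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), support = integer(0), run_lens = list(),
    members = list(), flags = character(0), pass = logical(0))
  if (nrow(anchors) == 0L) return(empty)
  out <- list()
  anchors <- data.table::copy(anchors)
  anchors[, grp := paste(chrom, strand)]
  for (g in unique(anchors$grp)) {
    a <- anchors[grp == g]
    cl <- chain_positions(a$start, cluster_window)
    for (cc in unique(cl)) {
      m <- a[cl == cc]
      out[[length(out) + 1L]] <- data.table::data.table(
        tumour_id = tumour_id, chrom = m$chrom[1],
        start = min(m$start), end = max(m$end), strand = m$strand[1],
        support = nrow(m), run_lens = list(m$run_len),
        members = list(m$qname))
    }
  }
  cands <- data.table::rbindlist(out)
  cands[, candidate_id := sprintf("%s_p%04d", tumour_id, .I)]
  cands[, flags := add_flag("", "insufficient-support",
                            support < min_support)]
  cands[, pass := flags == ""]
  data.table::setcolorder(cands, "candidate_id")
  cands[]
}

#' Subtract polyA evidence found in any normal
#'
#' Normals are scanned with the identical read flagging and anchoring logic
#' at a support threshold of one: a candidate is flagged when any normal
#' (matched or panel) has an anchored flagged read within `cluster_window`
#' of the candidate locus, strand-blind.
#'
#' @param cands candidates from [anchor_candidates()].
#' @param normal_anchors_list list of anchor tables, one per normal (the
#'   matched normal first by convention).
#' @param cluster_window matching window.
#' @return candidates with the `normal-support` flag applied.
#' @export
subtract_normals <- function(cands, normal_anchors_list, cluster_window) {
  if (nrow(cands) == 0L) return(cands)
  hit <- logical(nrow(cands))
  for (na in normal_anchors_list) {
    if (is.null(na) || nrow(na) == 0L) next
    for (i in seq_len(nrow(cands))) {
      if (hit[i]) next
      sel <- na$chrom == cands$chrom[i] &
        interval_gap(na$start, na$end, cands$start[i], cands$end[i]) <=
          cluster_window
      if (any(sel)) hit[i] <- TRUE
    }
  }
  cands[, flags := add_flag(flags, "normal-support", hit)]
  cands[, pass := flags == ""]
  cands[]
}

#' Flag candidates near reference polyA
#'
#' Inserts anchored within `window` of a reference polyA run cannot be
#' distinguished from mismapping around the run and are flagged.
#'
#' @param cands candidates.
#' @param polya_index [index_reference_polya()] table (min run 20).
#' @param window distance threshold (default 500; a gap of exactly 500 is
#'   still flagged, 501 is kept).
#' @return candidates with the `near-reference-polyA` flag applied.
#' @export
reference_polya_proximity_filter <- function(cands, polya_index,
                                             window = 500L) {
  if (nrow(cands) == 0L) return(cands)
  hit <- vapply(seq_len(nrow(cands)), function(i) {
    sel <- polya_index$chrom == cands$chrom[i]
    if (!any(sel)) return(FALSE)
    any(interval_gap(polya_index$start[sel], polya_index$end[sel],
                     cands$start[i], cands$end[i]) <= window)
  }, logical(1))
  cands[, flags := add_flag(flags, "near-reference-polyA", hit)]
  cands[, pass := flags == ""]
  cands[]
}

#' Scan one tumour for tumour-specific polyA insertions
#'
#' Full scanner: flag reads with >= `min_run` consecutive A/T, drop
#' unusable reads, anchor by mates mapped at MAPQ >= `mapq_min`, group into
#' candidates, subtract matched-normal and panel evidence, flag candidates
#' near reference polyA, and annotate against a polymorphism catalogue.
#'
#' @param tumour_aln tumour `alignment_set` (strict-dialect alignments).
#' @param normal_aln matched normal `alignment_set`.
#' @param panel_alns list of panel-normal `alignment_set`s.
#' @param genome `genome_model` (for the reference polyA index).
#' @param min_run,mapq_min,min_support,max_lowq_run,polya_window filter
#'   settings per the scan's definition.
#' @param cluster_window anchor linkage window; default
#'   `fragment_mean + 4*fragment_sd` from the genome config.
#' @param catalogue optional polymorphism catalogue (chrom, pos, id).
#' @param tumour_id label.
#' @return `polya_candidates` table with flags, pass status and
#'   polymorphism annotation.
#' @export
scan_polya <- function(tumour_aln, normal_aln, panel_alns = list(), genome,
                       min_run = 20L, mapq_min = 30L, min_support = 3L,
                       max_lowq_run = 80L, polya_window = 500L,
                       cluster_window = NULL, catalogue = NULL,
                       tumour_id = "tumour") {
  if (is.null(cluster_window)) {
    cfg <- genome$config
    cluster_window <- as.integer(cfg$fragment_mean + 4 * cfg$fragment_sd)
  }
  tanch <- polya_anchors(tumour_aln, min_run, max_lowq_run, mapq_min)
  cands <- anchor_candidates(tanch, cluster_window, min_support, tumour_id)
  normals <- c(list(normal_aln), panel_alns)
  nanch <- lapply(normals, polya_anchors, min_run = min_run,
                  max_lowq_run = max_lowq_run, mapq_min = mapq_min)
  cands <- subtract_normals(cands, nanch, cluster_window)
  polya_idx <- index_reference_polya(genome, min_run)
  cands <- reference_polya_proximity_filter(cands, polya_idx, polya_window)
  if (!is.null(catalogue) && nrow(cands) > 0) {
    mid <- as.integer((cands$start + cands$end) / 2)
    ann <- match_polymorphisms(
      data.frame(chrom = cands$chrom, pos = mid), catalogue)
    cands[, `:=`(poly_match = ann$poly_match, poly_dist = ann$poly_dist)]
  } else {
    cands[, `:=`(poly_match = NA_character_, poly_dist = NA_integer_)]
  }
  data.table::setattr(cands, "class",
                      c("polya_candidates", class(cands)))
  cands[]
}

#' @export
print.polya_candidates <- function(x, ...) {
  cat(sprintf("polya_candidates: %d candidate(s), %d PASS\n", nrow(x),
              sum(x$pass %in% TRUE)))
  if (nrow(x))
    print(utils::head(as.data.frame(
      x[, c("candidate_id", "chrom", "start", "end", "strand", "support",
            "flags", "pass")]), 10))
  invisible(x)
}

#' Tumour/normal swap control
#'
#' Repeats the identical scan with the tumour and its matched normal
#' interchanged; the swapped PASS count estimates the scan's artefact and
#' unsampled-polymorphism background.
#'
#' @inheritParams scan_polya
#' @param ... further arguments passed to [scan_polya()].
#' @return list with `forward_pass`, `swapped_pass` and both candidate
#'   tables.
#' @export
control_swap <- function(tumour_aln, normal_aln, panel_alns = list(), genome,
                         tumour_id = "tumour", ...) {
  fwd <- scan_polya(tumour_aln, normal_aln, panel_alns, genome,
                    tumour_id = tumour_id, ...)
  swp <- scan_polya(normal_aln, tumour_aln, panel_alns, genome,
                    tumour_id = paste0(tumour_id, "_swapped"), ...)
  list(forward_pass = sum(fwd$pass), swapped_pass = sum(swp$pass),
       forward = fwd, swapped = swp)
}

# modal value helper (smallest mode on ties, deterministic)
modal_value <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  as.integer(names(tb)[1])
}

oriented_clip_tails <- function(aln, side) {
  # side "right": tail clipped after the aligned segment at ref pos+alen;
  # side "left": tail clipped before the segment at ref pos.
  res <- list()
  for (m in 1:2) {
    g <- function(col) aln[[paste0(col, m)]]
    mapped <- !is.na(g("chrom"))
    oriented <- g("seq")
    neg <- mapped & g("strand") == "-"
    oriented[neg] <- revcomp(oriented[neg])
    L <- nchar(oriented)
    if (side == "right") {
      sel <- which(mapped & g("clipr") > 0L)
      point <- g("pos")[sel] + g("alen")[sel]
      tail <- substring(oriented[sel], g("clipl")[sel] + g("alen")[sel] + 1L,
                        L[sel])
    } else {
      sel <- which(mapped & g("clipl") > 0L)
      point <- g("pos")[sel]
      tail <- substring(oriented[sel], 1L, g("clipl")[sel])
    }
    if (length(sel))
      res[[m]] <- data.table::data.table(chrom = g("chrom")[sel],
                                         point = point, tail = tail,
                                         side = side)
  }
  data.table::rbindlist(Filter(Negate(is.null), res))
}

majority_consensus <- function(tails, from_end = FALSE) {
  if (length(tails) == 0L) return("")
  n <- max(nchar(tails))
  cons <- character(n)
  for (i in seq_len(n)) {
    ch <- vapply(tails, function(t) {
      k <- if (from_end) nchar(t) - i + 1L else i
      if (k >= 1L && k <= nchar(t)) substr(t, k, k) else NA_character_
    }, character(1))
    ch <- ch[!is.na(ch)]
    if (length(ch) == 0L) { cons[i] <- "N"; next }
    tb <- sort(table(ch), decreasing = TRUE)
    cons[i] <- names(tb)[1]
  }
  s <- paste(cons, collapse = "")
  if (from_end) paste(rev(strsplit(s, "")[[1]]), collapse = "") else s
}

#' Automated curation of a polyA candidate
#'
#' Inspects soft-clipped reads in a window around the candidate: the
#' insertion point is the modal clip coordinate (taking the reference
#' resumption side when both clip sides are seen), the clipped tails are
#' collapsed to a majority-vote consensus, and the consensus (or any clipped
#' tail of >= 25 bp) is compared against the donor L1 consensus at >= 90%
#' identity in either orientation.
#'
#' @param cand one candidate row (from [scan_polya()]).
#' @param tumour_aln,normal_aln alignment sets (soft-clip information is
#'   taken from the CIGARs).
#' @param genome `genome_model` (supplies the L1/Alu consensus sequences).
#' @param window half-width of the inspected region around the candidate
#'   anchor (default 300, i.e. an approximately 600 bp view).
#' @param min_clip minimum clipped-tail length considered (default 8).
#' @param polya_run_min clipped-tail A/T run declaring `contains_polyA`.
#' @param identity donor-match identity threshold.
#' @return a one-row `data.table` curation result; `informative = FALSE`
#'   when no clipped reads are found.
#' @export
curate_candidate <- function(cand, tumour_aln, normal_aln = NULL, genome,
                             window = 300L, min_clip = 8L,
                             polya_run_min = 10L, identity = 0.9,
                             clips = NULL, normal_clips = NULL) {
  lo <- cand$start - window; hi <- cand$end + window
  if (is.null(clips))
    clips <- data.table::rbindlist(list(
      oriented_clip_tails(tumour_aln, "right"),
      oriented_clip_tails(tumour_aln, "left")))
  clips <- clips[chrom == cand$chrom & point >= lo & point <= hi &
                 nchar(tail) >= min_clip]
  uninformative <- data.table::data.table(
    candidate_id = cand$candidate_id, informative = FALSE,
    n_clipped = 0L, insertion_point = NA_integer_,
    consensus = NA_character_, contains_L1 = NA, contains_polyA = NA,
    germline_evidence = NA_integer_)
  if (nrow(clips) == 0L) return(uninformative)
  # modal clip coordinate per side; the reference resumes at the smaller of
  # the two (the left-side TSD copy pushes right-clip points downstream)
  pt_right <- if (any(clips$side == "right"))
    modal_value(clips[side == "right"]$point) else NA_integer_
  pt_left <- if (any(clips$side == "left"))
    modal_value(clips[side == "left"]$point) else NA_integer_
  insertion_point <- suppressWarnings(min(pt_right, pt_left, na.rm = TRUE))
  here <- clips[abs(point - insertion_point) <= 25L]
  main_side <- if (sum(here$side == "right") >= sum(here$side == "left"))
    "right" else "left"
  tails <- here[side == main_side]$tail
  cons <- majority_consensus(tails, from_end = (main_side == "left"))
  probes <- unique(c(cons, tails[nchar(tails) >= 25L]))
  probes <- probes[nchar(probes) >= min_clip]
  ref_l1 <- c(genome$consensus_l1,
              vapply(genome$donors, `[[`, character(1), "element_seq"))
  contains_l1 <- FALSE
  for (p in probes) {
    w <- min(nchar(p), 25L)
    for (targ in ref_l1) {
      if (cpp_best_window_identity(p, targ, w) >= identity ||
          cpp_best_window_identity(revcomp(p), targ, w) >= identity) {
        contains_l1 <- TRUE; break
      }
    }
    if (contains_l1) break
  }
  runs <- find_polya_reads(probes, polya_run_min)
  contains_polya <- any(runs$flagged)
  germ <- 0L
  if (is.null(normal_clips) && !is.null(normal_aln))
    normal_clips <- data.table::rbindlist(list(
      oriented_clip_tails(normal_aln, "right"),
      oriented_clip_tails(normal_aln, "left")))
  if (!is.null(normal_clips))
    germ <- nrow(normal_clips[chrom == cand$chrom &
                              abs(point - insertion_point) <= 5L &
                              nchar(tail) >= min_clip])
  data.table::data.table(
    candidate_id = cand$candidate_id, informative = TRUE,
    n_clipped = nrow(here), insertion_point = as.integer(insertion_point),
    consensus = cons, contains_L1 = contains_l1,
    contains_polyA = contains_polya, germline_evidence = germ)
}

#' Curate all candidates of one tumour
#'
#' Precomputes the soft-clip tables once and applies [curate_candidate()]
#' to every candidate.
#'
#' @inheritParams curate_candidate
#' @param cands candidate table from [scan_polya()].
#' @return `data.table` of curation results, one row per candidate.
#' @export
curate_candidates <- function(cands, tumour_aln, normal_aln = NULL, genome,
                              window = 300L, min_clip = 8L,
                              polya_run_min = 10L, identity = 0.9) {
  clips <- data.table::rbindlist(list(
    oriented_clip_tails(tumour_aln, "right"),
    oriented_clip_tails(tumour_aln, "left")))
  nclips <- if (is.null(normal_aln)) NULL else data.table::rbindlist(list(
    oriented_clip_tails(normal_aln, "right"),
    oriented_clip_tails(normal_aln, "left")))
  data.table::rbindlist(lapply(seq_len(nrow(cands)), function(i)
    curate_candidate(cands[i], tumour_aln, normal_aln, genome, window,
                     min_clip, polya_run_min, identity, clips = clips,
                     normal_clips = nclips)))
}
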