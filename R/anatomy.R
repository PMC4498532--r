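# Structural anatomy of a resolved insert: target-site duplication, polyA
# tail, 5' (twin-priming) inversion, donor assignment, transduced extent and
# polyA addition site.

#' Detect the target-site duplication at an insertion
#'
#' Given the insert-bearing sequence with known insert boundaries and the
#' reference sequence resuming at the target, reports the longest exact
#' duplication L such that the L bases immediately left of the insert equal
#' the L bases immediately right of it and match the unduplicated reference
#' target. Length 0 is a blunt junction; when no duplication exists, a small
#' target deletion of up to `max_del` bases is searched for and reported as
#' a negative length.
#'
#' @param sequence insert-bearing sequence (e.g. the tumour allele with
#'   flanking context).
#' @param insert_start,insert_end 1-based inclusive bounds of the inserted
#'   material within `sequence`.
#' @param ref_target reference sequence starting at the nick position (what
#'   follows the target site in the unduplicated reference).
#' @param max_tsd maximum duplication searched (default 30).
#' @param max_del maximum deletion searched (default 10).
#' @param probe bases of right context used to anchor the deletion search.
#' @return list with `tsd_len` (negative = deletion) and `tsd_seq` (the
#'   duplicated bases, `""` if none).
#' @export
detect_tsd <- function(sequence, insert_start, insert_end, ref_target,
                       max_tsd = 30L, max_del = 10L, probe = 40L) {
  n <- nchar(sequence)
  if (insert_start < 1L || insert_end > n || insert_start > insert_end)
    stop("insert boundaries outside the sequence")
  best <- 0L
  for (L in seq_len(min(max_tsd, insert_start - 1L, n - insert_end,
                        nchar(ref_target)))) {
    left <- substr(sequence, insert_start - L, insert_start - 1L)
    right <- substr(sequence, insert_end + 1L, insert_end + L)
    if (left == right && left == substr(ref_target, 1L, L)) best <- L
  }
  if (best > 0L)
    return(list(tsd_len = best,
                tsd_seq = substr(sequence, insert_start - best,
                                 insert_start - 1L)))
  # blunt or deleted: find the smallest shift d of the reference that
  # matches the sequence right of the insert
  k <- min(probe, n - insert_end, nchar(ref_target) - max_del)
  if (k >= 10L) {
    right <- substr(sequence, insert_end + 1L, insert_end + k)
    for (d in 0:max_del) {
      if (substr(ref_target, d + 1L, d + k) == right)
        return(list(tsd_len = -d, tsd_seq = ""))
    }
  }
  list(tsd_len = 0L, tsd_seq = "")
}

#' Measure the polyA tail of an insert
#'
#' Maximal qualifying suffix: the tail is anchored at the insert 3' end
#' (which must be A), and a non-A base is absorbed only when at least nine
#' consecutive As continue the tail immediately 5' of it -- at most one
#' non-A per ten bases, absorbing polymerase slippage without running into
#' A-rich upstream insert sequence.
#'
#' @param insert_seq insert sequence, 5'->3', tail at the 3' end.
#' @return tail length in bp (0 when the insert does not end in A).
#' @export
measure_polya_tail <- function(insert_seq) {
  n <- nchar(insert_seq)
  if (n == 0L || substr(insert_seq, n, n) != "A") return(0L)
  ch <- strsplit(insert_seq, "")[[1]]
  len <- 0L
  i <- n
  while (i >= 1L) {
    if (ch[i] == "A") {
      len <- len + 1L
    } else {
      if (i - 9L < 1L || any(ch[(i - 9L):(i - 1L)] != "A")) break
      len <- len + 1L
    }
    i <- i - 1L
  }
  len
}

# longest suffix of `x` occurring exactly in `subject`; binary search is
# valid because a suffix of an occurring suffix also occurs
longest_matching_suffix <- function(x, subject) {
  n <- nchar(x)
  lo <- 0L; hi <- n
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (grepl(substr(x, n - mid + 1L, n), subject, fixed = TRUE)) lo <- mid
    else hi <- mid - 1L
  }
  lo
}

#' Detect a 5' (twin-priming) inversion
#'
#' If a 5' prefix of at least `min_prefix` bases matches the donor sequence
#' reverse-complemented while the remainder matches forward downstream of
#' it, the insert carries the sequence signature of twin priming: the
#' prefix length and the donor-offset gap between the inverted segment and
#' the forward segment are reported.
#'
#' @param body insert sequence without the polyA tail, 5'->3'.
#' @param donor_seq donor sequence (element + transducible flank) the insert
#'   was assigned to.
#' @param min_prefix minimum inverted prefix length (default 10).
#' @return list: `status` (`"none"`, `"partial_5prime"` or
#'   `"whole_insert"`), and for partial inversions `inv_len` and `inv_gap`.
#' @export
detect_inversion <- function(body, donor_seq, min_prefix = 10L) {
  none <- list(status = "none", inv_len = NA_integer_, inv_gap = NA_integer_)
  n <- nchar(body)
  if (n < min_prefix) return(none)
  l_fwd <- longest_matching_suffix(body, donor_seq)
  if (l_fwd == n) return(none)  # fully forward-matching
  if (l_fwd < min_prefix && grepl(revcomp(body), donor_seq, fixed = TRUE))
    return(list(status = "whole_insert", inv_len = n, inv_gap = NA_integer_))
  # the matching suffix may overrun the true split by a few coincidental
  # bases; prefer the longest prefix that validates as an inversion
  for (l in max(1L, l_fwd - 3L):l_fwd) {
    prefix <- substr(body, 1L, n - l)
    if (nchar(prefix) < min_prefix) next
    rc <- revcomp(prefix)
    r_positions <- gregexpr(rc, donor_seq, fixed = TRUE)[[1]]
    if (r_positions[1] == -1L) next
    fwd_seg <- substr(body, n - l + 1L, n)
    q_positions <- gregexpr(fwd_seg, donor_seq, fixed = TRUE)[[1]]
    if (q_positions[1] == -1L) next
    best <- NULL
    for (r in r_positions) for (q in q_positions) {
      gap <- q - (r + nchar(prefix))
      if (gap >= 0L && (is.null(best) || gap < best)) best <- gap
    }
    if (!is.null(best))
      return(list(status = "partial_5prime", inv_len = nchar(prefix),
                  inv_gap = as.integer(best)))
  }
  none
}

#' Assign an insert to its donor element
#'
#' Scores the insert body against each donor's element + transducible flank
#' concatenation (local alignment); ties between family copies are broken
#' by the per-copy diagnostic bases carried by the insert. Reports identity,
#' the matched donor interval, the transduced flank interval and the
#' L1-content fraction (matched element bases over non-polyA insert
#' length; 0 for flank-only inserts).
#'
#' @param body insert sequence without the polyA tail, 5'->3' (de-inverted
#'   if an inversion was detected, though partial inversions only shorten
#'   the matched interval).
#' @param donors a [donor_library()].
#' @param min_identity assignments below this identity are flagged
#'   unassigned (default 0.8).
#' @param min_coverage minimum fraction of the body the local alignment must
#'   span for an assignment (guards against short coincidental matches).
#' @return list: donor id (or NA), identity, matched donor-cat interval,
#'   transduced flank interval (NULL if none), L1 content fraction,
#'   `assigned` flag.
#' @export
assign_donor <- function(body, donors, min_identity = 0.8,
                         min_coverage = 0.5) {
  if (nchar(body) == 0L)
    return(list(donor = NA_character_, identity = NA_real_, sub_start = NA,
                sub_end = NA, transduced = NULL, l1_fraction = NA_real_,
                assigned = FALSE))
  # fast exact route: donors containing the body's 3' end verbatim
  probe <- substr(body, max(1L, nchar(body) - 29L), nchar(body))
  hit <- names(donors)[vapply(donors, function(d)
    grepl(probe, d$cat, fixed = TRUE), logical(1))]
  cand <- if (length(hit) > 0) donors[hit] else donors
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                 baseOnly = TRUE)
  score_one <- function(d) {
    al <- Biostrings::pairwiseAlignment(body, d$cat, type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = 5, gapExtension = 2)
    list(score = Biostrings::score(al),
         identity = Biostrings::pid(al) / 100,
         sub_start = Biostrings::start(Biostrings::subject(al)),
         sub_end = Biostrings::end(Biostrings::subject(al)),
         matched = Biostrings::nchar(al))
  }
  res <- lapply(cand, score_one)
  scores <- vapply(res, `[[`, numeric(1), "score")
  top <- which(scores == max(scores))
  if (length(top) > 1L) {
    # tie-break by diagnostic bases present in the insert
    ndiag <- vapply(top, function(i) {
      d <- cand[[i]]
      sum(vapply(seq_len(nrow(d$diagnostic)), function(k) {
        off <- d$diagnostic$offset[k]
        s <- res[[i]]$sub_start; e <- res[[i]]$sub_end
        off >= s && off <= e
      }, logical(1)))
    }, numeric(1))
    top <- top[order(-ndiag, names(cand)[top])][1]
  } else top <- top[1]
  d <- cand[[top]]; r <- res[[top]]
  elen <- nchar(d$element)
  el_bases <- max(0L, min(r$sub_end, elen) - r$sub_start + 1L)
  tr <- NULL
  if (r$sub_end > elen)
    tr <- c(max(1L, r$sub_start - elen), r$sub_end - elen)
  list(donor = d$id, identity = r$identity, sub_start = r$sub_start,
       sub_end = r$sub_end, transduced = tr,
       l1_fraction = el_bases / nchar(body),
       assigned = r$identity >= min_identity &&
         r$matched >= min_coverage * nchar(body))
}

#' PolyA addition site of an insert
#'
#' The genomic coordinate of the last transduced base before the tail;
#' element-only inserts report the element 3' end, and polyA-only inserts
#' have no defined site.
#'
#' @param donor one entry of [donor_library()].
#' @param transduced transduced flank interval from [assign_donor()] (or
#'   `NULL`).
#' @param element_only `TRUE` when the insert matched the element but no
#'   flank.
#' @return genomic coordinate (integer) or `NA`.
#' @export
polya_addition_site <- function(donor, transduced, element_only = FALSE) {
  if (!is.null(transduced)) {
    off <- transduced[2]
    return(as.integer(if (donor$strand == "+") donor$flank_start - 1L + off
                      else donor$flank_end + 1L - off))
  }
  if (element_only) {
    el_end <- if (donor$in_reference) {
      # 3' end of the element body in genomic coordinates
      if (donor$strand == "+") donor$flank_start - 1L - donor$tail_len
      else donor$flank_end + 1L + donor$tail_len
    } else NA_integer_
    return(as.integer(el_end))
  }
  NA_integer_
}

#' Full anatomy of one resolved insert
#'
#' Orients the insert by its polyA tail, measures the tail, detects the
#' target-site duplication against the reference target, assigns the donor,
#' detects a 5' inversion and locates the polyA addition site.
#'
#' @param sequence insert-bearing sequence with flanking context.
#' @param insert_start,insert_end insert bounds within `sequence` (1-based
#'   inclusive).
#' @param ref_target reference sequence resuming at the nick (see
#'   [detect_tsd()]).
#' @param donors a [donor_library()].
#' @param max_tsd,max_del TSD search caps.
#' @return one-row `data.table` with tsd length/sequence, orientation, tail
#'   length, non-polyA length, donor id and identity, L1 fraction,
#'   transduced extent, inversion status and polyA addition site.
#' @export
anatomize_insert <- function(sequence, insert_start, insert_end, ref_target,
                             donors, max_tsd = 30L, max_del = 10L) {
  tsd <- detect_tsd(sequence, insert_start, insert_end, ref_target, max_tsd,
                    max_del)
  ins <- substr(sequence, insert_start, insert_end)
  fwd_tail <- measure_polya_tail(ins)
  rev_tail <- measure_polya_tail(revcomp(ins))
  orientation <- if (rev_tail > fwd_tail) "-" else "+"
  oriented <- if (orientation == "-") revcomp(ins) else ins
  tail_len <- max(fwd_tail, rev_tail)
  body <- substr(oriented, 1L, nchar(oriented) - tail_len)
  non_polya <- nchar(body)
  asg <- assign_donor(body, donors)
  inv <- if (asg$assigned)
    detect_inversion(body, donors[[asg$donor]]$cat) else
    list(status = "none", inv_len = NA_integer_, inv_gap = NA_integer_)
  transduced_extent <- if (!is.null(asg$transduced))
    asg$transduced[2] else 0L
  site <- if (asg$assigned)
    polya_addition_site(donors[[asg$donor]], asg$transduced,
                        element_only = is.null(asg$transduced)) else
    NA_integer_
  data.table::data.table(
    tsd_len = tsd$tsd_len, tsd_seq = tsd$tsd_seq,
    orientation = orientation, insert_len = nchar(ins),
    tail_len = as.integer(tail_len), non_polya_len = as.integer(non_polya),
    donor = asg$donor, identity = asg$identity,
    l1_fraction = asg$l1_fraction, assigned = asg$assigned,
    transduced_extent = as.integer(transduced_extent),
    inversion = inv$status, inv_len = inv$inv_len, inv_gap = inv$inv_gap,
    polya_site = site)
}

#' Rebuild resolved insert contexts from simulation truth
#'
#' Reconstructs, from the reference and a truth row, the local tumour
#' allele (left context + TSD + insert + right context) exactly as the
#' tumour genome carries it, together with the reference target sequence
#' needed by [detect_tsd()].
#'
#' @param genome `genome_model`.
#' @param truth truth table rows from [simulate_tumour()].
#' @param context flanking context length (default 300).
#' @return `data.table` with insert_id, sequence, insert bounds and
#'   ref_target.
#' @export
resolved_from_truth <- function(genome, truth, context = 300L) {
  out <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    refseq <- genome$seqs[[tr$chrom]]
    p <- tr$pos; t <- tr$tsd
    left <- substr(refseq, p - context, if (t > 0) p + t - 1L else p - 1L)
    resume <- if (t < 0) p - t else p
    right <- substr(refseq, resume, resume + context - 1L)
    data.table::data.table(
      insert_id = tr$insert_id, tumour_id = tr$tumour_id,
      sequence = paste0(left, tr$insert_seq, right),
      insert_start = nchar(left) + 1L,
      insert_end = nchar(left) + nchar(tr$insert_seq),
      ref_target = substr(refseq, p, p + context + 50L))
  })
  data.table::rbindlist(out)
}

#' Anatomize all inserts of a study or truth table
#'
#' @param genome `genome_model`.
#' @param truth truth rows.
#' @param donors optional precomputed [donor_library()].
#' @return anatomy `data.table`, one row per insert, joined with insert ids.
#' @export
anatomize_truth <- function(genome, truth, donors = donor_library(genome)) {
  if (nrow(truth) == 0L) return(data.table::data.table())
  resolved <- resolved_from_truth(genome, truth)
  res <- data.table::rbindlist(lapply(seq_len(nrow(resolved)), function(i) {
    r <- resolved[i, ]
    cbind(data.table::data.table(insert_id = r$insert_id,
                                 tumour_id = r$tumour_id),
          anatomize_insert(r$sequence, r$insert_start, r$insert_end,
                           r$ref_target, donors))
  }))
  res
}
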