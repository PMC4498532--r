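# Somatic rearrangement-junction calling from discordant read pairs.
#
# A discordant pair reports two breakpoint loci with directions: "+" means
# the joined partner sequence continues to the right of the breakpoint (the
# read aligned on the plus strand, junction past its 3' end), "-" to the
# left. Pairs are canonicalised so side A <= side B by (chrom, pos).

mate_breakpoint <- function(pos, alen, strand) {
  ifelse(strand == "+", pos + alen - 1L, pos)
}

#' Extract discordant pairs from an alignment set
#'
#' A pair is concordant when the mates are inner-facing on opposite strands
#' of one chromosome within `mean + 4*sd` of fragment length; anything else
#' with both mates mapped is discordant. Duplicates and mates below
#' `min_mapq` are excluded.
#'
#' @param aln an `alignment_set`.
#' @param frag_stats list(mean=, sd=) from [estimate_fragment_stats()]; if
#'   `NULL` it is estimated from the concordant pairs of `aln`.
#' @param min_mapq minimum MAPQ for both mates (default 1: exclude only
#'   ambiguous MAPQ-0 placements).
#' @return a `data.table` of discordant pairs: qname, chromA/posA/dirA,
#'   chromB/posB/dirB and the discordance class (`inter_chromosomal`,
#'   `long_range`, `aberrant_orientation`).
#' @export
extract_discordant <- function(aln, frag_stats = NULL, min_mapq = 1L) {
  if (is.null(frag_stats)) frag_stats <- estimate_fragment_stats(aln)
  thr <- frag_stats$mean + 4 * frag_stats$sd
  both <- !is.na(aln$chrom1) & !is.na(aln$chrom2) & !aln$dup &
    aln$mapq1 >= min_mapq & aln$mapq2 >= min_mapq
  x <- aln[both]
  same <- x$chrom1 == x$chrom2
  opp <- x$strand1 != x$strand2
  inner <- opp & same &
    ((x$strand1 == "+" & x$pos1 <= x$pos2 + x$alen2) |
     (x$strand2 == "+" & x$pos2 <= x$pos1 + x$alen1))
  spanlen <- ifelse(x$strand1 == "+", x$pos2 + x$alen2 - x$pos1,
                    x$pos1 + x$alen1 - x$pos2)
  concordant <- same & inner & spanlen > 0 & spanlen <= thr
  cls <- ifelse(!same, "inter_chromosomal",
         ifelse(inner & spanlen > thr, "long_range", "aberrant_orientation"))
  d <- x[!concordant]
  cls <- cls[!concordant]
  if (nrow(d) == 0L) return(empty_discordant())
  bp1 <- mate_breakpoint(d$pos1, d$alen1, d$strand1)
  bp2 <- mate_breakpoint(d$pos2, d$alen2, d$strand2)
  dir1 <- d$strand1
  dir2 <- d$strand2
  first_is_a <- (d$chrom1 < d$chrom2) | (d$chrom1 == d$chrom2 & bp1 <= bp2)
  out <- data.table::data.table(
    qname = d$qname,
    chromA = ifelse(first_is_a, d$chrom1, d$chrom2),
    posA = ifelse(first_is_a, bp1, bp2),
    dirA = ifelse(first_is_a, dir1, dir2),
    chromB = ifelse(first_is_a, d$chrom2, d$chrom1),
    posB = ifelse(first_is_a, bp2, bp1),
    dirB = ifelse(first_is_a, dir2, dir1),
    class = cls)
  out
}

empty_discordant <- function() {
  data.table::data.table(qname = character(0), chromA = character(0),
                         posA = integer(0), dirA = character(0),
                         chromB = character(0), posB = integer(0),
                         dirB = character(0), class = character(0))
}

# connected components under the subcluster predicate:
# same orientation group (handled by the caller) and both sides within
# `window`. Positions are pre-partitioned on side A (no edge can cross an
# A-gap > window), then components are found exactly.
subcluster_components <- function(posA, posB, window) {
  n <- length(posA)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  o <- order(posA)
  blocks <- chain_positions(posA, window)
  for (b in unique(blocks)) {
    sel <- which(blocks == b)
    if (length(sel) < 2L) next
    for (ii in seq_along(sel)) for (jj in seq_len(ii - 1L)) {
      i <- sel[ii]; j <- sel[jj]
      if (abs(posA[i] - posA[j]) <= window && abs(posB[i] - posB[j]) <= window)
        unite(i, j)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cluster discordant pairs into junction calls
#'
#' Pairs with identical side chromosomes and directions whose breakpoints
#' chain within `window` on both sides form one subcluster supporting a
#' single junction; the breakpoint estimate is the innermost read end on
#' each side.
#'
#' @param pairs output of [extract_discordant()].
#' @param window linkage window; default `fragment_mean + 4*fragment_sd`
#'   should be supplied by the caller.
#' @param tumour_id label stored on the calls.
#' @return a `junction_calls` `data.table`: one row per subcluster with
#'   breakpoints, directions, support and member read names.
#' @export
cluster_pairs <- function(pairs, window, tumour_id = NA_character_) {
  if (nrow(pairs) == 0L) return(empty_junctions())
  pairs <- data.table::copy(pairs)
  pairs[, grp := paste(chromA, dirA, chromB, dirB)]
  out <- list()
  for (g in unique(pairs$grp)) {
    p <- pairs[grp == g]
    comp <- subcluster_components(p$posA, p$posB, window)
    for (cc in unique(comp)) {
      m <- p[comp == cc]
      out[[length(out) + 1L]] <- data.table::data.table(
        tumour_id = tumour_id,
        chromA = m$chromA[1], dirA = m$dirA[1],
        posA = if (m$dirA[1] == "+") max(m$posA) else min(m$posA),
        chromB = m$chromB[1], dirB = m$dirB[1],
        posB = if (m$dirB[1] == "+") max(m$posB) else min(m$posB),
        support = nrow(m), class = m$class[1],
        members = list(m$qname))
    }
  }
  calls <- data.table::rbindlist(out)
  calls[, junction_id := sprintf("%s_j%04d", tumour_id, .I)]
  calls[, `:=`(normal_support = NA_integer_, panel_support = NA_integer_,
               flags = "", pass = NA, partner_id = NA_character_)]
  data.table::setattr(calls, "class", c("junction_calls", class(calls)))
  calls[]
}

empty_junctions <- function() {
  calls <- data.table::data.table(
    tumour_id = character(0), chromA = character(0), dirA = character(0),
    posA = integer(0), chromB = character(0), dirB = character(0),
    posB = integer(0), support = integer(0), class = character(0),
    members = list(), junction_id = character(0),
    normal_support = integer(0), panel_support = integer(0),
    flags = character(0), pass = logical(0), partner_id = character(0))
  data.table::setattr(calls, "class", c("junction_calls", class(calls)))
  calls
}

#' @export
print.junction_calls <- function(x, ...) {
  cat(sprintf("junction_calls: %d call(s), %d PASS\n", nrow(x),
              sum(x$pass %in% TRUE)))
  if (nrow(x)) {
    show <- x[, c("junction_id", "chromA", "posA", "dirA", "chromB", "posB",
                  "dirB", "support", "normal_support", "panel_support",
                  "flags", "pass")]
    print(utils::head(as.data.frame(show), 10))
    if (nrow(x) > 10) cat("...\n")
  }
  invisible(x)
}

add_flag <- function(flags, which, add) {
  ifelse(add, ifelse(flags == "", which, paste(flags, which, sep = ",")),
         flags)
}

count_matching_pairs <- function(call, pairs, window) {
  if (nrow(pairs) == 0L) return(0L)
  direct <- pairs$chromA == call$chromA & pairs$chromB == call$chromB &
    pairs$dirA == call$dirA & pairs$dirB == call$dirB &
    abs(pairs$posA - call$posA) <= window &
    abs(pairs$posB - call$posB) <= window
  sum(direct)
}

#' Subtract matched-normal and panel-of-normals evidence
#'
#' A call is contaminated when any normal (matched or panel) has a
#' discordant pair matching both sides within `window` with the same
#' directions; contaminated calls and calls below `min_support` are flagged.
#'
#' @param calls `junction_calls` from [cluster_pairs()].
#' @param normal_pairs discordant pairs of the matched normal (may be empty).
#' @param panel_pairs list of discordant-pair tables, one per panel normal.
#' @param window matching window (same scale as the clustering window).
#' @param min_support minimum tumour read-pair support (default 3; batches
#'   with few library artefacts may use 2).
#' @return the calls with `normal_support`, `panel_support`, flags and the
#'   `pass` status filled in.
#' @export
filter_by_normals <- function(calls, normal_pairs, panel_pairs = list(),
                              window, min_support = 3L) {
  if (nrow(calls) == 0L) return(calls)
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i]
    data.table::set(calls, i, "normal_support",
                    count_matching_pairs(cl, normal_pairs, window))
    data.table::set(calls, i, "panel_support",
                    sum(vapply(panel_pairs, function(pp)
                      count_matching_pairs(cl, pp, window), integer(1))))
  }
  calls[, flags := add_flag(flags, "insufficient-support",
                            support < min_support)]
  calls[, flags := add_flag(flags, "normal-contaminated",
                            normal_support > 0L | panel_support > 0L)]
  calls[, pass := flags == ""]
  calls[]
}

#' Flag small inversion-type calls
#'
#' Libraries whose preparation circularised single-stranded fragments show
#' artefactual small inversions; intra-chromosomal aberrant-orientation
#' calls spanning less than `min_size` are flagged when enabled.
#'
#' @param calls `junction_calls`.
#' @param min_size span threshold (default 10000; a span of exactly
#'   `min_size` is kept).
#' @param enabled logical; typically on for strict-dialect libraries.
#' @return calls with the `small-inversion` flag applied.
#' @export
filter_small_inversions <- function(calls, min_size = 10000L, enabled = TRUE) {
  if (!enabled || nrow(calls) == 0L) return(calls)
  inv <- calls$chromA == calls$chromB & calls$dirA == calls$dirB &
    abs(calls$posB - calls$posA) < min_size
  calls[, flags := add_flag(flags, "small-inversion", inv)]
  calls[, pass := flags == ""]
  calls[]
}

#' Drop calls explainable by a plausible normal alignment
#'
#' Compares +/-500 bp windows around the two breakpoints by an ungapped
#' sliding scan (both orientations); a call is flagged when any offset
#' reaches at least `min_identity` over at least `min_len` aligned bases,
#' since the read clusters could then simply be mismapped copies of one
#' locus.
#'
#' @param calls `junction_calls`.
#' @param genome `genome_model` or named chromosome sequences.
#' @param window half-width of the compared windows (clipped at chromosome
#'   bounds).
#' @param min_len,min_identity the match rule (defaults 100 bp, 90%).
#' @param only_pass only evaluate calls currently passing (the scan is the
#'   expensive step).
#' @return calls with the `plausible-normal-alignment` flag applied.
#' @export
plausible_normal_alignment_filter <- function(calls, genome, window = 500L,
                                              min_len = 100L,
                                              min_identity = 0.9,
                                              only_pass = TRUE) {
  if (nrow(calls) == 0L) return(calls)
  seqs <- if (inherits(genome, "genome_model")) genome$seqs else genome
  ctx <- function(chrom, pos) {
    n <- nchar(seqs[[chrom]])
    substr(seqs[[chrom]], max(1L, pos - window), min(n, pos + window))
  }
  idx <- if (only_pass) which(calls$pass %in% c(TRUE, NA)) else
    seq_len(nrow(calls))
  hit <- logical(nrow(calls))
  for (i in idx) {
    a <- ctx(calls$chromA[i], calls$posA[i])
    b <- ctx(calls$chromB[i], calls$posB[i])
    ident <- max(cpp_best_window_identity(a, b, min_len),
                 cpp_best_window_identity(a, revcomp(b), min_len))
    hit[i] <- ident >= min_identity
  }
  calls[, flags := add_flag(flags, "plausible-normal-alignment", hit)]
  calls[, pass := flags == ""]
  calls[]
}

#' Pair reciprocal junctions of two-ended insertions
#'
#' The two junctions of one insertion share a target locus (breakpoints
#' within `window_target`, opposite directions) while their far sides sit on
#' one chromosome within `window_far` in opposite directions; for 3'
#' transductions the far sides straddle the transduced tract, so
#' `window_far` must cover the transduced extent (default 2000 bp).
#'
#' @param calls `junction_calls` from one tumour.
#' @param window_target window on the shared (insertion-target) side;
#'   default 50 bp covers target-site duplications up to 20 bp plus
#'   breakpoint-estimate noise.
#' @param window_far window on the far side.
#' @return calls with `partner_id` filled for paired junctions.
#' @export
pair_reciprocal_junctions <- function(calls, window_target = 50L,
                                      window_far = 2000L) {
  n <- nrow(calls)
  if (n < 2L) return(calls)
  side_match <- function(i, j, si, sj, win, need_opposite = TRUE) {
    ci <- calls[[paste0("chrom", si)]][i]; cj <- calls[[paste0("chrom", sj)]][j]
    pi <- calls[[paste0("pos", si)]][i];  pj <- calls[[paste0("pos", sj)]][j]
    di <- calls[[paste0("dir", si)]][i];  dj <- calls[[paste0("dir", sj)]][j]
    ci == cj && abs(pi - pj) <= win && (!need_opposite || di != dj)
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!is.na(calls$partner_id[i]) || !is.na(calls$partner_id[j])) next
    ok <-
      (side_match(i, j, "A", "A", window_target) &&
       side_match(i, j, "B", "B", window_far)) ||
      (side_match(i, j, "B", "B", window_target) &&
       side_match(i, j, "A", "A", window_far)) ||
      (side_match(i, j, "A", "B", window_target) &&
       side_match(i, j, "B", "A", window_far)) ||
      (side_match(i, j, "B", "A", window_target) &&
       side_match(i, j, "A", "B", window_far))
    if (ok) {
      data.table::set(calls, i, "partner_id", calls$junction_id[j])
      data.table::set(calls, j, "partner_id", calls$junction_id[i])
    }
  }
  calls[]
}

#' Call somatic junctions for one tumour
#'
#' Convenience wrapper chaining discordant-pair extraction, subclustering,
#' normal subtraction, the small-inversion and plausible-normal-alignment
#' filters and reciprocal pairing.
#'
#' @param tumour_aln tumour `alignment_set`.
#' @param normal_aln matched-normal `alignment_set` (extracted identically).
#' @param panel_alns list of panel-normal `alignment_set`s.
#' @param genome `genome_model`.
#' @param min_support,min_mapq,small_inversion_min,small_inversion_enabled
#'   filter settings (see the individual operations).
#' @param tumour_id label for the calls.
#' @param frag_stats optional precomputed fragment stats.
#' @return `junction_calls` with all filters applied.
#' @export
call_junctions <- function(tumour_aln, normal_aln, panel_alns = list(),
                           genome, min_support = 3L, min_mapq = 1L,
                           small_inversion_min = 10000L,
                           small_inversion_enabled = TRUE,
                           tumour_id = "tumour", frag_stats = NULL) {
  if (is.null(frag_stats)) frag_stats <- estimate_fragment_stats(tumour_aln)
  window <- as.integer(frag_stats$mean + 4 * frag_stats$sd)
  tpairs <- extract_discordant(tumour_aln, frag_stats, min_mapq)
  npairs <- extract_discordant(normal_aln, frag_stats, min_mapq)
  ppairs <- lapply(panel_alns, extract_discordant, frag_stats = frag_stats,
                   min_mapq = min_mapq)
  calls <- cluster_pairs(tpairs, window, tumour_id)
  calls <- filter_by_normals(calls, npairs, ppairs, window, min_support)
  calls <- filter_small_inversions(calls, small_inversion_min,
                                   small_inversion_enabled)
  calls <- plausible_normal_alignment_filter(calls, genome)
  calls <- pair_reciprocal_junctions(calls)
  calls
}

#' Write junction calls as TSV and BEDPE
#'
#' TSV coordinates are 1-based inclusive; BEDPE intervals are 0-based
#' half-open points at the breakpoints.
#'
#' @param calls `junction_calls`.
#' @param tsv,bedpe output paths (`NULL` to skip either).
#' @return invisibly, the paths written.
#' @export
write_junctions <- function(calls, tsv = NULL, bedpe = NULL) {
  flat <- as.data.frame(calls[, !"members"])
  flat$members <- vapply(calls$members, paste, character(1), collapse = ";")
  if (!is.null(tsv))
    utils::write.table(flat, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bedpe)) {
    bp <- data.frame(chrom1 = flat$chromA, start1 = flat$posA - 1L,
                     end1 = flat$posA, chrom2 = flat$chromB,
                     start2 = flat$posB - 1L, end2 = flat$posB,
                     name = flat$junction_id, score = flat$support,
                     strand1 = flat$dirA, strand2 = flat$dirB)
    utils::write.table(bp, bedpe, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(tsv, bedpe))
}

#' Read junction calls written by [write_junctions()]
#' @param path TSV path.
#' @return a `junction_calls` table.
#' @export
read_junctions <- function(path) {
  flat <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, na.strings = "NA")
  calls <- data.table::as.data.table(flat)
  calls[, members := strsplit(as.character(flat$members), ";", fixed = TRUE)]
  calls[, tumour_id := as.character(tumour_id)]
  if (is.null(calls$split_mapping)) calls[, split_mapping := NA]
  data.table::setattr(calls, "class",
                      c("junction_calls", class(calls)))
  calls[]
}
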