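# Source-element discovery: recurrent breakpoint clusters across tumours,
# their classification into the three ways mobile-element inserts surface in
# paired-end data (transduced unique sequence, confident mapping to a
# reference element or polyA run, and artefactual "split mappings"), plus
# the reference polyA index and polymorphism-catalogue matching.

#' Index polyA runs of the reference
#'
#' Maximal homopolymer A and T runs of at least `min_run` bases (a T run is
#' a minus-strand polyA). Ranked by decreasing length for rank queries such
#' as "longest run in the reference".
#'
#' @param genome `genome_model` or named chromosome sequences.
#' @param min_run minimum run length (default 20).
#' @return `data.table` with chrom, start, end (1-based inclusive), length,
#'   base, strand and rank.
#' @export
index_reference_polya <- function(genome, min_run = 20L) {
  seqs <- if (inherits(genome, "genome_model")) genome$seqs else genome
  out <- lapply(names(seqs), function(cn) {
    runs <- cpp_find_runs(seqs[[cn]], min_run, "AT")
    if (nrow(runs) == 0L) return(NULL)
    data.table::data.table(chrom = cn, start = runs$start, end = runs$end,
                           length = runs$end - runs$start + 1L,
                           base = runs$base,
                           strand = ifelse(runs$base == "A", "+", "-"))
  })
  idx <- data.table::rbindlist(Filter(Negate(is.null), out))
  if (nrow(idx) == 0L) {
    idx <- data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), length = integer(0),
                                  base = character(0), strand = character(0))
  }
  data.table::setorder(idx, -length, chrom, start)
  idx[, rank := seq_len(.N)]
  idx[]
}

#' Find recurrent breakpoint clusters across tumours
#'
#' Both breakpoints of every call are chained per chromosome with
#' single-linkage at `chain_window`; a chained group is reported when it
#' holds at least `min_junctions` junctions from at least `min_tumours`
#' tumours. Distinct partner loci (the far breakpoints of the members,
#' merged at `chain_window`) distinguish these many-partner insertion
#' sources from genuine recurrent rearrangements.
#'
#' @param calls `junction_calls` pooled across tumours (typically PASS only).
#' @param chain_window linkage window (default 1000).
#' @param min_junctions,min_tumours reporting thresholds (defaults 5 and 2).
#' @return `data.table` of clusters: locus, member junction ids, tumours,
#'   span, distinct partner count.
#' @export
find_breakpoint_clusters <- function(calls, chain_window = 1000L,
                                     min_junctions = 5L, min_tumours = 2L) {
  empty <- data.table::data.table(
    cluster_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), span = integer(0), n_junctions = integer(0),
    n_tumours = integer(0), n_partner_loci = integer(0), members = list())
  if (nrow(calls) == 0L) return(empty)
  bps <- data.table::rbindlist(list(
    calls[, .(junction_id, tumour_id, chrom = chromA, pos = posA,
              pchrom = chromB, ppos = posB)],
    calls[, .(junction_id, tumour_id, chrom = chromB, pos = posB,
              pchrom = chromA, ppos = posA)]))
  out <- list()
  for (cn in unique(bps$chrom)) {
    b <- bps[chrom == cn]
    b[, grp := chain_positions(pos, chain_window)]
    for (g in unique(b$grp)) {
      m <- b[grp == g]
      if (length(unique(m$junction_id)) < min_junctions) next
      if (length(unique(m$tumour_id)) < min_tumours) next
      # partner loci merged at the chaining scale, per partner chromosome
      np <- sum(vapply(split(m$ppos, m$pchrom), function(pp)
        length(unique(chain_positions(pp, chain_window))), integer(1)))
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = cn, start = min(m$pos), end = max(m$pos),
        span = max(m$pos) - min(m$pos), n_junctions = length(unique(m$junction_id)),
        n_tumours = length(unique(m$tumour_id)), n_partner_loci = np,
        members = list(unique(m$junction_id)))
    }
  }
  if (length(out) == 0L) return(empty)
  cl <- data.table::rbindlist(out)
  cl[, cluster_id := sprintf("cluster_%03d", seq_len(.N))]
  data.table::setcolorder(cl, "cluster_id")
  cl[]
}

#' Group junctions near the 3' ends of known active L1s
#'
#' A discovery aid independent of recurrence thresholds: breakpoints inside
#' a listed hot L1 or within `downstream_window` 3' of its end (strand
#' aware) are grouped per element.
#'
#' @param calls `junction_calls` pooled across tumours.
#' @param hot_l1 BED-like data.frame (chrom, start, end, name, score,
#'   strand; 0-based half-open as read by [read_bed()]) or the same columns
#'   1-based via `one_based = TRUE`.
#' @param downstream_window bp downstream of the 3' end (default 5000).
#' @param one_based set when `hot_l1` is already 1-based inclusive.
#' @return `data.table`: element, junction ids, junction and tumour counts.
#' @export
find_hot_l1_proximal <- function(calls, hot_l1, downstream_window = 5000L,
                                 one_based = FALSE) {
  if (is.null(hot_l1$strand) || any(!hot_l1$strand %in% c("+", "-")))
    stop("hot L1 annotation requires a +/- strand column")
  start1 <- if (one_based) hot_l1$start else hot_l1$start + 1L
  end1 <- hot_l1$end
  out <- list()
  bps <- data.table::rbindlist(list(
    calls[, .(junction_id, tumour_id, chrom = chromA, pos = posA)],
    calls[, .(junction_id, tumour_id, chrom = chromB, pos = posB)]))
  for (i in seq_len(nrow(hot_l1))) {
    lo <- if (hot_l1$strand[i] == "+") start1[i] else start1[i] - downstream_window
    hi <- if (hot_l1$strand[i] == "+") end1[i] + downstream_window else end1[i]
    m <- bps[chrom == hot_l1$chrom[i] & pos >= lo & pos <= hi]
    if (nrow(m) == 0L) next
    out[[length(out) + 1L]] <- data.table::data.table(
      element = hot_l1$name[i], chrom = hot_l1$chrom[i],
      n_breakpoints = nrow(m),
      n_junctions = length(unique(m$junction_id)),
      n_tumours = length(unique(m$tumour_id)),
      members = list(unique(m$junction_id)))
  }
  if (length(out) == 0L)
    return(data.table::data.table(element = character(0), chrom = character(0),
                                  n_breakpoints = integer(0),
                                  n_junctions = integer(0),
                                  n_tumours = integer(0), members = list()))
  data.table::rbindlist(out)
}

# annotation bundle used by classification; built from a genome_model
discovery_annotations <- function(genome, polya_min_run = 20L) {
  el <- genome$elements
  nonref <- Filter(function(d) !d$in_reference, genome$donors)
  list(
    elements = el,
    nonref = if (length(nonref))
      data.frame(id = vapply(nonref, `[[`, character(1), "id"),
                 chrom = vapply(nonref, `[[`, character(1), "chrom"),
                 pos = vapply(nonref, `[[`, integer(1), "insertion_point"),
                 stringsAsFactors = FALSE)
      else data.frame(id = character(0), chrom = character(0),
                      pos = integer(0)),
    polya = index_reference_polya(genome, polya_min_run))
}

element_downstream <- function(el, downstream_window) {
  lo <- ifelse(el$strand == "+", el$end + 1L, el$start - downstream_window)
  hi <- ifelse(el$strand == "+", el$end + downstream_window, el$start - 1L)
  data.frame(lo = lo, hi = hi)
}

#' Classify a breakpoint cluster as a source-element call
#'
#' Precedence: (1) cluster in unique sequence within `downstream_window` 3'
#' of an annotated reference L1 is a reference-L1 transduction; (2) cluster
#' within `nonref_window` of a catalogued non-reference donor insertion
#' point is a non-reference transduction; (3) cluster overlapping an element
#' 3' terminus (last `terminus_window` bp) or a polyA run of at least 20 bp
#' is a reference-element mapping; (4) otherwise unclassified. The maximum
#' transduced extent is the farthest member breakpoint 3' of the donor end.
#'
#' @param cluster one row of [find_breakpoint_clusters()].
#' @param annotations list with `elements` (1-based data.frame incl. strand
#'   and family), `nonref` (id, chrom, pos) and `polya`
#'   ([index_reference_polya()] table); see also [discovery_annotations()].
#' @param downstream_window,nonref_window,terminus_window rule windows.
#' @return one-row `data.table`: cluster id/locus, label, matched annotation
#'   and max transduced extent (bp).
#' @export
classify_cluster <- function(cluster, annotations, downstream_window = 5000L,
                             nonref_window = 1000L, terminus_window = 500L) {
  lab <- "unclassified"; match_id <- NA_character_; extent <- NA_integer_
  el <- annotations$elements
  l1 <- el[el$family == "L1", , drop = FALSE]
  done <- FALSE
  if (nrow(l1) > 0) {
    dw <- element_downstream(l1, downstream_window)
    # the cluster must reach unique sequence 3' of the element; it may also
    # include breakpoints inside the element 3' end (severely truncated
    # inserts carry both element and transduced sequence)
    hit <- which(l1$chrom == cluster$chrom &
                 cluster$start <= dw$hi & cluster$end >= dw$lo)
    if (length(hit) > 0) {
      i <- hit[which.min(pmax(0L, ifelse(l1$strand[hit] == "+",
                                         cluster$start - l1$end[hit],
                                         l1$start[hit] - cluster$end)))]
      lab <- "transduction_reference_L1"; match_id <- l1$id[i]
      extent <- if (l1$strand[i] == "+") cluster$end - l1$end[i] else
        l1$start[i] - cluster$start
      done <- TRUE
    }
  }
  if (!done && nrow(annotations$nonref) > 0) {
    nr <- annotations$nonref
    d <- ifelse(nr$chrom == cluster$chrom,
                interval_gap(cluster$start, cluster$end, nr$pos, nr$pos),
                NA_integer_)
    hit <- which(!is.na(d) & d <= nonref_window)
    if (length(hit) > 0) {
      i <- hit[which.min(d[hit])]
      lab <- "transduction_nonreference_L1"; match_id <- nr$id[i]
      extent <- max(abs(c(cluster$start, cluster$end) - nr$pos[i]))
      done <- TRUE
    }
  }
  if (!done) {
    hit_run <- annotations$polya[chrom == cluster$chrom &
                                 start <= cluster$end & end >= cluster$start]
    term <- el
    if (nrow(el) > 0) {
      tlo <- ifelse(el$strand == "+", pmax(el$start, el$end - terminus_window + 1L),
                    el$start)
      thi <- ifelse(el$strand == "+", el$end,
                    pmin(el$end, el$start + terminus_window - 1L))
      hit_el <- which(el$chrom == cluster$chrom &
                      cluster$start <= thi & cluster$end >= tlo)
    } else hit_el <- integer(0)
    if (nrow(hit_run) > 0 || length(hit_el) > 0) {
      lab <- "reference_element_mapping"
      match_id <- if (length(hit_el) > 0) el$id[hit_el[1]] else
        sprintf("polyA_run_%s_%d", hit_run$chrom[1], hit_run$start[1])
    }
  }
  data.table::data.table(cluster_id = cluster$cluster_id,
                         chrom = cluster$chrom, start = cluster$start,
                         end = cluster$end, n_junctions = cluster$n_junctions,
                         n_tumours = cluster$n_tumours, label = lab,
                         match_id = match_id,
                         max_transduced = as.integer(extent),
                         members = list(cluster$members[[1]]))
}

#' Classify all clusters
#' @param clusters table from [find_breakpoint_clusters()].
#' @inheritParams classify_cluster
#' @return `data.table` of source-element calls (one row per cluster).
#' @export
classify_clusters <- function(clusters, annotations, downstream_window = 5000L,
                              nonref_window = 1000L, terminus_window = 500L) {
  if (nrow(clusters) == 0L)
    return(classify_cluster(
      data.table::data.table(cluster_id = "x", chrom = "x", start = 1L,
                             end = 1L, n_junctions = 0L, n_tumours = 0L,
                             members = list(character(0))),
      annotations)[0])
  data.table::rbindlist(lapply(seq_len(nrow(clusters)), function(i)
    classify_cluster(clusters[i], annotations, downstream_window,
                     nonref_window, terminus_window)))
}

# MEI-associated loci: transduced-flank windows of transduction calls,
# element 3' termini and polyA runs
mei_loci <- function(element_calls, annotations, downstream_window = 5000L,
                     terminus_window = 500L) {
  loci <- list()
  el <- annotations$elements
  if (!is.null(el) && nrow(el) > 0) {
    tlo <- ifelse(el$strand == "+", pmax(el$start, el$end - terminus_window + 1L),
                  el$start)
    thi <- ifelse(el$strand == "+", el$end,
                  pmin(el$end, el$start + terminus_window - 1L))
    loci[[1]] <- data.frame(chrom = el$chrom, lo = tlo, hi = thi)
  }
  if (nrow(annotations$polya) > 0)
    loci[[length(loci) + 1L]] <- with(annotations$polya,
      data.frame(chrom = chrom, lo = start, hi = end))
  tr <- element_calls[element_calls$label %in%
                        c("transduction_reference_L1",
                          "transduction_nonreference_L1"), , drop = FALSE]
  if (nrow(tr) > 0)
    loci[[length(loci) + 1L]] <- data.frame(chrom = tr$chrom, lo = tr$start,
                                            hi = tr$end)
  if (length(loci) == 0L)
    return(data.frame(chrom = character(0), lo = integer(0), hi = integer(0)))
  do.call(rbind, loci)
}

in_loci <- function(chrom, pos, loci, pad = 0L) {
  if (nrow(loci) == 0L) return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i)
    any(loci$chrom == chrom[i] & pos[i] >= loci$lo - pad &
        pos[i] <= loci$hi + pad), logical(1))
}

#' Detect split mappings
#'
#' A junction whose both breakpoints fall in mobile-element-associated loci
#' (transduced flanks of classified source elements, element 3' termini,
#' reference polyA runs) is an artefact of two reads from inside one insert
#' being placed at two different loci; such junctions are labelled and
#' excluded from per-tumour insert counts.
#'
#' @param calls `junction_calls`.
#' @param element_calls classified clusters from [classify_clusters()].
#' @param annotations as in [classify_cluster()].
#' @param pad slack around the loci (default 200 bp).
#' @return calls with a logical `split_mapping` column.
#' @export
detect_split_mappings <- function(calls, element_calls, annotations,
                                  pad = 200L) {
  loci <- mei_loci(element_calls, annotations)
  calls[, split_mapping := in_loci(chromA, posA, loci, pad) &
          in_loci(chromB, posB, loci, pad)]
  calls[]
}

#' Match candidate sites against a polymorphism catalogue
#'
#' Nearest catalogue entry within `window`, without considering strand or
#' read direction.
#'
#' @param sites data.frame with chrom and pos (1-based).
#' @param catalogue data.frame with chrom, pos and id.
#' @param window maximum distance (default 1000; boundary inclusive).
#' @return `data.table` of sites with `poly_match` and `poly_dist`.
#' @export
match_polymorphisms <- function(sites, catalogue, window = 1000L) {
  sites <- data.table::as.data.table(sites)
  sites[, `:=`(poly_match = NA_character_, poly_dist = NA_integer_)]
  if (nrow(sites) == 0L || is.null(catalogue) || nrow(catalogue) == 0L)
    return(sites[])
  for (i in seq_len(nrow(sites))) {
    sel <- which(catalogue$chrom == sites$chrom[i])
    if (length(sel) == 0L) next
    d <- abs(catalogue$pos[sel] - sites$pos[i])
    j <- which.min(d)
    if (d[j] <= window) {
      data.table::set(sites, i, "poly_match", catalogue$id[sel[j]])
      data.table::set(sites, i, "poly_dist", as.integer(d[j]))
    }
  }
  sites[]
}
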