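# Gene intersection, recurrence and the per-tumour / per-element summary
# tables.

#' Intersect insertion sites with gene intervals
#'
#' Point-in-interval test on the insertion point. Relative orientation
#' compares the insert's polyA strand with the gene strand; it is unknown
#' when either strand is missing, and carries a caveat flag when the call
#' rests on a single junction (a 5' inversion can then mislead the
#' orientation).
#'
#' @param sites data.frame: insert_id, chrom, pos, optional strand and
#'   optional `single_junction` logical.
#' @param genes data.frame: gene, chrom, start, end (1-based inclusive),
#'   strand; strand may be missing (`NA`/`.`), in which case orientation is
#'   unknown.
#' @param tumour_id optional vector aligned with `sites`.
#' @return `data.table` of gene annotations (one row per site-in-gene).
#' @export
intersect_genes <- function(sites, genes, tumour_id = NULL) {
  empty <- data.table::data.table(
    insert_id = character(0), tumour_id = character(0), gene = character(0),
    gene_strand = character(0), orientation = character(0),
    orientation_caveat = logical(0))
  if (is.null(sites) || nrow(sites) == 0L || is.null(genes) ||
      nrow(genes) == 0L) return(empty)
  if (is.null(tumour_id))
    tumour_id <- if (!is.null(sites$tumour_id)) sites$tumour_id else
      rep(NA_character_, nrow(sites))
  out <- list()
  for (cn in unique(sites$chrom)) {
    si <- which(sites$chrom == cn)
    gi <- which(genes$chrom == cn)
    if (length(gi) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos[si], sites$pos[si]),
      IRanges::IRanges(genes$start[gi], genes$end[gi]))
    if (length(ov) == 0L) next
    s <- si[S4Vectors::queryHits(ov)]
    g <- gi[S4Vectors::subjectHits(ov)]
    istr <- if (!is.null(sites$strand)) sites$strand[s] else
      rep(NA_character_, length(s))
    gstr <- genes$strand[g]
    known <- !is.na(istr) & istr %in% c("+", "-") &
      !is.na(gstr) & gstr %in% c("+", "-")
    orient <- ifelse(!known, "unknown",
                     ifelse(istr == gstr, "same", "opposite"))
    caveat <- if (!is.null(sites$single_junction))
      sites$single_junction[s] %in% TRUE else rep(FALSE, length(s))
    out[[length(out) + 1L]] <- data.table::data.table(
      insert_id = sites$insert_id[s], tumour_id = tumour_id[s],
      gene = genes$gene[g], gene_strand = gstr, orientation = orient,
      orientation_caveat = caveat)
  }
  if (length(out) == 0L) return(empty)
  data.table::rbindlist(out)
}

#' Rank genes by recurrent insertion across tumours
#'
#' Counts distinct tumours per gene; multiple inserts of one gene in the
#' same tumour are reported separately as multiplicity (they may reflect a
#' single complex event rather than independent insertions).
#'
#' @param annotations output of [intersect_genes()] across tumours.
#' @return `data.table` ranked by tumour count: gene, n_tumours,
#'   n_inserts, max_per_tumour.
#' @export
recurrence <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L)
    return(data.table::data.table(gene = character(0),
                                  n_tumours = integer(0),
                                  n_inserts = integer(0),
                                  max_per_tumour = integer(0)))
  ann <- data.table::as.data.table(annotations)
  out <- ann[, .(n_tumours = length(unique(tumour_id)), n_inserts = .N,
                 max_per_tumour = max(table(tumour_id))), by = gene]
  data.table::setorder(out, -n_tumours, -n_inserts, gene)
  out[]
}

# count distinct inserts among PASS non-split junctions: reciprocal
# partners collapse to one insert
count_inserts <- function(calls) {
  sel <- calls$pass %in% TRUE & !(calls$split_mapping %in% TRUE)
  x <- calls[sel]
  if (nrow(x) == 0L) return(0L)
  paired <- !is.na(x$partner_id) & x$partner_id %in% x$junction_id
  as.integer(nrow(x) - sum(paired) / 2)
}

#' Per-tumour activity summary
#'
#' One row per tumour: number of distinct transduction-class source
#' elements active, inserts found by discordant pairs (PASS junctions,
#' split mappings excluded, reciprocal junction pairs counted once),
#' inserts mapped to reference elements/polyA pooled separately (their
#' source cannot be attributed to a specific element), and PASS polyA-scan
#' candidates. A final row holds the batch means.
#'
#' @param calls_by_tumour named list of `junction_calls` (with
#'   `split_mapping` filled).
#' @param element_calls classified clusters ([classify_clusters()] output).
#' @param polya_by_tumour named list of candidate tables.
#' @return `data.table`.
#' @export
per_tumour_summary <- function(calls_by_tumour, element_calls,
                               polya_by_tumour) {
  tumours <- names(calls_by_tumour)
  transduction <- element_calls[element_calls$label %in%
    c("transduction_reference_L1", "transduction_nonreference_L1"), ,
    drop = FALSE]
  rows <- lapply(tumours, function(tid) {
    calls <- calls_by_tumour[[tid]]
    active <- 0L
    unattributed <- 0L
    if (nrow(calls) > 0) {
      ids <- calls$junction_id[calls$pass %in% TRUE]
      active <- sum(vapply(seq_len(nrow(transduction)), function(i)
        any(transduction$members[[i]] %in% ids), logical(1)))
      ref_el <- element_calls[element_calls$label == "reference_element_mapping", ,
                              drop = FALSE]
      unattributed <- sum(vapply(seq_len(nrow(ref_el)), function(i)
        sum(ref_el$members[[i]] %in% ids), integer(1)))
    }
    pa <- polya_by_tumour[[tid]]
    data.table::data.table(
      tumour_id = tid, elements_active = active,
      inserts_discordant = count_inserts(calls),
      element_mapped_junctions = unattributed,
      polya_candidates = if (is.null(pa)) NA_integer_ else
        sum(pa$pass %in% TRUE))
  })
  tab <- data.table::rbindlist(rows)
  means <- tab[, lapply(.SD, function(x) round(mean(x, na.rm = TRUE), 1)),
               .SDcols = setdiff(names(tab), "tumour_id")]
  data.table::rbindlist(list(tab, cbind(tumour_id = "mean", means)),
                        use.names = TRUE)
}

#' Per-element summary
#'
#' One row per classified source element: label, locus, total inserts
#' (member junctions, reciprocal pairs counted once), tumour count,
#' discovery method (breakpoint cluster and/or hot-L1 proximity), maximum
#' transduced extent and the polyA addition sites observed in the insert
#' anatomy.
#'
#' @param element_calls classified clusters.
#' @param calls_all pooled `junction_calls` across tumours.
#' @param anatomy optional anatomy table ([anatomize_truth()]-shaped) whose
#'   `donor` and `polya_site` columns supply observed addition sites.
#' @param hot_hits optional [find_hot_l1_proximal()] table marking elements
#'   also found via the hot-L1 list.
#' @return `data.table`.
#' @export
per_element_summary <- function(element_calls, calls_all, anatomy = NULL,
                                hot_hits = NULL) {
  if (nrow(element_calls) == 0L)
    return(data.table::data.table(
      element = character(0), label = character(0), locus = character(0),
      total_inserts = integer(0), n_tumours = integer(0),
      method = character(0), max_transduced = integer(0),
      polya_sites = character(0)))
  rows <- lapply(seq_len(nrow(element_calls)), function(i) {
    ec <- element_calls[i]
    mem <- ec$members[[1]]
    sub <- calls_all[calls_all$junction_id %in% mem]
    paired <- !is.na(sub$partner_id) & sub$partner_id %in% sub$junction_id
    total <- as.integer(nrow(sub) - sum(paired) / 2)
    method <- "Cl"
    if (!is.null(hot_hits) && nrow(hot_hits) > 0 &&
        !is.na(ec$match_id) && ec$match_id %in% hot_hits$element)
      method <- "Cl,L1"
    sites <- ""
    if (!is.null(anatomy) && nrow(anatomy) > 0 && !is.na(ec$match_id)) {
      ss <- anatomy[anatomy$donor %in% ec$match_id & !is.na(anatomy$polya_site), ]
      if (nrow(ss) > 0) {
        tb <- sort(table(ss$polya_site), decreasing = TRUE)
        sites <- paste(sprintf("%s(x%d)", names(tb), as.integer(tb)),
                       collapse = ";")
      }
    }
    data.table::data.table(
      element = ec$match_id, label = ec$label,
      locus = sprintf("%s:%d-%d", ec$chrom, ec$start, ec$end),
      total_inserts = total,
      n_tumours = ec$n_tumours, method = method,
      max_transduced = ec$max_transduced, polya_sites = sites)
  })
  data.table::rbindlist(rows)
}
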