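# End-to-end synthetic study: simulate reference + tumour/normal/panel
# individuals, sequence and align every sample, then run junction calling,
# source-element discovery, the polyA scan with swap control and curation,
# insert anatomy and the summary tables. Memory is kept bounded by reducing
# each sample's alignments to the small tables the callers need before the
# next sample is processed.

reduce_sample <- function(aln, frag_stats, min_mapq = 1L) {
  list(
    frag_stats = frag_stats,
    discordant = extract_discordant(aln, frag_stats, min_mapq),
    anchors = polya_anchors(aln),
    clips = data.table::rbindlist(list(oriented_clip_tails(aln, "right"),
                                       oriented_clip_tails(aln, "left"))))
  }

process_sample <- function(seqs, genome, config, sample_id, dialect = "strict") {
  reads <- generate_read_pairs(seqs, config, sample_id)
  aln <- align_pairs(reads, genome, dialect)
  rm(reads)
  fs <- estimate_fragment_stats(aln)
  red <- reduce_sample(aln, fs)
  rm(aln)
  red
}

#' Run the full synthetic tumour/normal study
#'
#' Builds the reference, simulates `n_tumours` tumour/matched-normal
#' individuals plus `n_panel_normals` panel individuals and a zero-insert
#' negative-control tumour, sequences and aligns every sample (strict
#' dialect), and runs the complete detection pipeline: junction calling
#' with matched-normal/panel subtraction, cross-tumour source-element
#' discovery and classification, split-mapping detection, the polyA scan
#' with swap control and split-read curation, insert anatomy from the
#' simulated truth, gene annotation and the summary tables.
#'
#' @param config a [sim_config()].
#' @param curate run split-read curation of PASS polyA candidates (the
#'   slowest reporting step).
#' @param zero_control include a zero-insert control tumour.
#' @param min_support junction/polyA support threshold (default 3).
#' @param progress print stage progress.
#' @return a `retroscan_study` list: genome, truths, per-tumour junction
#'   calls and polyA candidates, element calls, anatomy, summaries and
#'   controls.
#' @export
run_study <- function(config, curate = TRUE, zero_control = TRUE,
                      min_support = 3L, progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  say("building reference")
  genome <- build_reference(config)
  ann <- discovery_annotations(genome)
  window <- as.integer(config$fragment_mean + 4 * config$fragment_sd)

  say("simulating and aligning panel normals")
  panel <- list()
  for (i in seq_len(config$n_panel_normals)) {
    pid <- sprintf("P%02d", i)
    indiv <- simulate_individual(genome, config, pid)
    panel[[pid]] <- process_sample(indiv$seqs, genome, config, pid)
  }

  tumour_ids <- sprintf("T%02d", seq_len(config$n_tumours))
  truths <- list(); tum <- list(); nor <- list()
  for (tid in tumour_ids) {
    say("simulating and aligning %s", tid)
    sim <- simulate_tumour(genome, config, tid)
    truths[[tid]] <- sim$truth
    tum[[tid]] <- process_sample(sim$tumour, genome, config, tid)
    nor[[tid]] <- process_sample(sim$normal, genome, config,
                                 paste0(tid, "N"))
    rm(sim)
  }
  truth_all <- data.table::rbindlist(truths)

  say("junction calling")
  panel_pairs <- lapply(panel, `[[`, "discordant")
  calls_by_tumour <- list()
  for (tid in tumour_ids) {
    calls <- cluster_pairs(tum[[tid]]$discordant, window, tid)
    calls <- filter_by_normals(calls, nor[[tid]]$discordant, panel_pairs,
                               window, min_support)
    calls <- filter_small_inversions(calls)
    calls <- plausible_normal_alignment_filter(calls, genome)
    calls <- pair_reciprocal_junctions(calls)
    calls_by_tumour[[tid]] <- calls
  }
  calls_all <- data.table::rbindlist(calls_by_tumour)

  say("element discovery")
  pass_all <- calls_all[calls_all$pass %in% TRUE]
  clusters <- find_breakpoint_clusters(pass_all)
  element_calls <- classify_clusters(clusters, ann)
  hot_bed <- do.call(rbind, lapply(
    Filter(function(d) isTRUE(d$hot), genome$donors), function(d)
      data.frame(chrom = d$chrom, start = d$start, end = d$end, name = d$id,
                 score = 0L, strand = d$strand, stringsAsFactors = FALSE)))
  hot_hits <- if (!is.null(hot_bed))
    find_hot_l1_proximal(pass_all, hot_bed, one_based = TRUE) else NULL
  for (tid in tumour_ids)
    calls_by_tumour[[tid]] <- detect_split_mappings(calls_by_tumour[[tid]],
                                                    element_calls, ann)
  calls_all <- data.table::rbindlist(calls_by_tumour)

  say("polyA scan")
  polya_idx <- index_reference_polya(genome)
  catalogue <- if (nrow(ann$nonref) > 0) ann$nonref else NULL
  panel_anchors <- lapply(panel, `[[`, "anchors")
  polya_by_tumour <- list(); swap <- list()
  for (tid in tumour_ids) {
    cands <- anchor_candidates(tum[[tid]]$anchors, window, min_support, tid)
    cands <- subtract_normals(cands, c(list(nor[[tid]]$anchors),
                                       panel_anchors), window)
    cands <- reference_polya_proximity_filter(cands, polya_idx)
    if (!is.null(catalogue) && nrow(cands) > 0) {
      mid <- as.integer((cands$start + cands$end) / 2)
      pm <- match_polymorphisms(data.frame(chrom = cands$chrom, pos = mid),
                                catalogue)
      cands[, `:=`(poly_match = pm$poly_match, poly_dist = pm$poly_dist)]
    }
    polya_by_tumour[[tid]] <- cands
    swapped <- anchor_candidates(nor[[tid]]$anchors, window, min_support,
                                 paste0(tid, "_swapped"))
    swapped <- subtract_normals(swapped, c(list(tum[[tid]]$anchors),
                                           panel_anchors), window)
    swapped <- reference_polya_proximity_filter(swapped, polya_idx)
    swap[[tid]] <- swapped
  }

  curation <- NULL
  if (curate) {
    say("curating PASS candidates")
    curation <- list()
    for (tid in tumour_ids) {
      cands <- polya_by_tumour[[tid]]
      pass <- cands[cands$pass %in% TRUE]
      if (nrow(pass) == 0L) next
      curation[[tid]] <- data.table::rbindlist(
        lapply(seq_len(nrow(pass)), function(i)
          curate_candidate(pass[i], NULL, NULL, genome,
                           clips = tum[[tid]]$clips,
                           normal_clips = nor[[tid]]$clips)))
    }
    curation <- data.table::rbindlist(curation, idcol = "tumour_id")
  }

  zero <- NULL
  if (zero_control) {
    say("zero-insert control tumour")
    zid <- "TZ0"
    sim <- simulate_tumour(genome, config, zid, n_inserts = 0L)
    zt <- process_sample(sim$tumour, genome, config, zid)
    zn <- process_sample(sim$normal, genome, config, paste0(zid, "N"))
    zcalls <- cluster_pairs(zt$discordant, window, zid)
    zcalls <- filter_by_normals(zcalls, zn$discordant, panel_pairs, window,
                                min_support)
    zcalls <- filter_small_inversions(zcalls)
    zcalls <- plausible_normal_alignment_filter(zcalls, genome)
    zcands <- anchor_candidates(zt$anchors, window, min_support, zid)
    zcands <- subtract_normals(zcands, c(list(zn$anchors), panel_anchors),
                               window)
    zcands <- reference_polya_proximity_filter(zcands, polya_idx)
    zero <- list(calls = zcalls, candidates = zcands)
    rm(sim, zt, zn)
  }

  say("anatomy and summaries")
  anatomy <- anatomize_truth(genome, truth_all)
  gene_sites <- if (nrow(truth_all) > 0)
    data.frame(insert_id = truth_all$insert_id,
               tumour_id = truth_all$tumour_id, chrom = truth_all$chrom,
               pos = truth_all$pos, strand = truth_all$orientation,
               stringsAsFactors = FALSE) else NULL
  gene_ann <- intersect_genes(gene_sites, genome$genes)
  summary_tumour <- per_tumour_summary(calls_by_tumour, element_calls,
                                       polya_by_tumour)
  summary_element <- per_element_summary(element_calls, calls_all, anatomy,
                                         hot_hits)

  out <- list(config = config, genome = genome, truth = truth_all,
              calls_by_tumour = calls_by_tumour, calls_all = calls_all,
              clusters = clusters, element_calls = element_calls,
              hot_hits = hot_hits, polya_by_tumour = polya_by_tumour,
              swap = swap, curation = curation, zero_control = zero,
              anatomy = anatomy, gene_annotation = gene_ann,
              recurrence = recurrence(gene_ann),
              summary_tumour = summary_tumour,
              summary_element = summary_element,
              window = window)
  class(out) <- "retroscan_study"
  out
}

#' @export
print.retroscan_study <- function(x, ...) {
  cat("retroscan synthetic study\n")
  cat(sprintf("  %d tumour(s), %d somatic inserts simulated\n",
              x$config$n_tumours, nrow(x$truth)))
  cat(sprintf("  PASS junctions: %d | source-element clusters: %d | PASS polyA candidates: %d\n",
              sum(x$calls_all$pass %in% TRUE), nrow(x$element_calls),
              sum(vapply(x$polya_by_tumour, function(p)
                sum(p$pass %in% TRUE), integer(1)))))
  invisible(x)
}

match_any_side <- function(calls, truth, window) {
  # for each call: TRUE if either breakpoint lies within window of a truth
  # target of the same tumour
  vapply(seq_len(nrow(calls)), function(i) {
    tt <- truth[truth$tumour_id == calls$tumour_id[i], ]
    if (nrow(tt) == 0L) return(FALSE)
    any((tt$chrom == calls$chromA[i] & abs(tt$pos - calls$posA[i]) <= window) |
        (tt$chrom == calls$chromB[i] & abs(tt$pos - calls$posB[i]) <= window))
  }, logical(1))
}

#' Evaluate a study against its simulation truth
#'
#' Computes the detection metrics: junction PASS precision and sensitivity
#' (for inserts carrying at least `min_transduced` bp of uniquely mappable
#' transduced sequence), polyA-scan PASS sensitivity (inserts with tails of
#' at least 25 bp) and false-site fraction, source-element recovery with
#' correct class labels, curation insertion-point accuracy (within 5 bp),
#' swap-control background and the zero-insert control counts.
#'
#' @param study a `retroscan_study`.
#' @param min_transduced junction-sensitivity denominator threshold
#'   (default 50 bp).
#' @return named list of metrics (fractions in 0..1 unless named `_pct`).
#' @export
evaluate_study <- function(study, min_transduced = 50L) {
  truth <- study$truth
  window <- study$window
  calls <- study$calls_all
  pass <- calls[calls$pass %in% TRUE & !(calls$split_mapping %in% TRUE)]
  tp <- if (nrow(pass)) match_any_side(pass, truth, window) else logical(0)
  junction_precision <- if (nrow(pass)) mean(tp) else NA_real_

  pass_tid <- pass[["tumour_id"]]
  det <- truth[truth$transduced >= min_transduced, ]
  junction_sensitivity <- if (nrow(det)) mean(vapply(seq_len(nrow(det)),
    function(i) {
      sel <- pass_tid == det$tumour_id[i]
      pp <- pass[sel]
      if (nrow(pp) == 0L) return(FALSE)
      any((pp$chromA == det$chrom[i] & abs(pp$posA - det$pos[i]) <= window) |
          (pp$chromB == det$chrom[i] & abs(pp$posB - det$pos[i]) <= window))
    }, logical(1))) else NA_real_

  cands <- data.table::rbindlist(study$polya_by_tumour)
  cpass <- cands[cands$pass %in% TRUE]
  cpass_tid <- cpass[["tumour_id"]]
  cpass_chrom <- cpass[["chrom"]]
  polya_hit <- if (nrow(cpass)) vapply(seq_len(nrow(cpass)), function(i) {
    tt <- truth[truth$tumour_id == cpass$tumour_id[i] &
                truth$chrom == cpass$chrom[i], ]
    if (nrow(tt) == 0L) return(FALSE)
    any(interval_gap(cpass$start[i], cpass$end[i], tt$pos, tt$pos) <= window)
  }, logical(1)) else logical(0)
  polya_false_rate <- if (nrow(cpass)) mean(!polya_hit) else NA_real_
  tails <- truth[truth$tail_len >= 25L, ]
  polya_sensitivity <- if (nrow(tails)) mean(vapply(seq_len(nrow(tails)),
    function(i) {
      sel <- cpass_tid == tails$tumour_id[i] & cpass_chrom == tails$chrom[i]
      cc <- cpass[sel]
      if (nrow(cc) == 0L) return(FALSE)
      any(interval_gap(cc$start, cc$end, tails$pos[i], tails$pos[i]) <=
            window)
    }, logical(1))) else NA_real_

  # donors owed a cluster: >= 5 truth-matched PASS junctions in >= 2 tumours
  owed <- character(0)
  if (nrow(pass) && nrow(truth)) {
    att <- lapply(seq_len(nrow(pass)), function(i) {
      tt <- truth[truth$tumour_id == pass$tumour_id[i], ]
      hit <- tt[(tt$chrom == pass$chromA[i] &
                 abs(tt$pos - pass$posA[i]) <= window) |
                (tt$chrom == pass$chromB[i] &
                 abs(tt$pos - pass$posB[i]) <= window), ]
      if (nrow(hit)) data.table::data.table(donor = hit$donor[1],
                                            tumour = pass$tumour_id[i])
      else NULL
    })
    att <- data.table::rbindlist(Filter(Negate(is.null), att))
    if (nrow(att)) {
      per <- att[, .(n = .N, nt = length(unique(tumour))), by = donor]
      owed <- per[n >= 5L & nt >= 2L]$donor
    }
  }
  donor_lib <- donor_library(study$genome)
  recovered <- vapply(owed, function(dn) {
    expect_label <- if (donor_lib[[dn]]$in_reference)
      "transduction_reference_L1" else "transduction_nonreference_L1"
    any(study$element_calls$label == expect_label &
        study$element_calls$match_id == dn)
  }, logical(1))
  donor_recovery <- if (length(owed)) mean(recovered) else NA_real_

  curation_acc <- NA_real_
  if (!is.null(study$curation) && nrow(study$curation) > 0) {
    cur <- study$curation[study$curation$informative %in% TRUE, ]
    if (nrow(cur) > 0) {
      ok <- vapply(seq_len(nrow(cur)), function(i) {
        tt <- truth[truth$tumour_id == cur$tumour_id[i], ]
        any(abs(tt$pos - cur$insertion_point[i]) <= 5L)
      }, logical(1))
      curation_acc <- mean(ok)
    }
  }

  fwd <- sum(vapply(study$polya_by_tumour, function(p)
    sum(p$pass %in% TRUE), integer(1)))
  swp <- sum(vapply(study$swap, function(p)
    sum(p$pass %in% TRUE), integer(1)))
  # the proximity filter's discard fraction is assessed among
  # tumour-specific candidates, i.e. those surviving support and normal
  # subtraction (reference-tail pileups are already removed by the normals)
  tspec <- cands[!grepl("insufficient-support|normal-support", cands$flags)]
  near_ref <- if (nrow(tspec)) mean(grepl("near-reference-polyA",
                                          tspec$flags)) else NA_real_

  zero_pass_junctions <- if (!is.null(study$zero_control))
    sum(study$zero_control$calls$pass %in% TRUE) else NA_integer_
  zero_pass_polya <- if (!is.null(study$zero_control))
    sum(study$zero_control$candidates$pass %in% TRUE) else NA_integer_

  list(junction_precision = junction_precision,
       junction_sensitivity = junction_sensitivity,
       polya_sensitivity = polya_sensitivity,
       polya_false_rate = polya_false_rate,
       donor_recovery = donor_recovery,
       donors_owed = length(owed),
       curation_within_5bp = curation_acc,
       swap_pass = swp, forward_pass = fwd,
       swap_over_forward = if (fwd > 0) swp / fwd else NA_real_,
       near_reference_polya_fraction = near_ref,
       zero_pass_junctions = zero_pass_junctions,
       zero_pass_polya = zero_pass_polya)
}
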