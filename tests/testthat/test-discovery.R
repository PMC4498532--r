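# Source-element discovery: polyA index, clusters, classification,
# split mappings and polymorphism matching.

test_that("polyA run indexing is exact, ranked and boundary-correct", {
  seqs <- c(chr1 = paste0("C", strrep("A", 90), "G"))
  idx <- index_reference_polya(seqs)
  expect_equal(nrow(idx), 1L)
  expect_equal(idx$length, 90L)
  expect_equal(idx$start, 2L)
  expect_equal(idx$end, 91L)
  # 19 As below min_run 20 are not reported
  expect_equal(nrow(index_reference_polya(c(c1 = strrep("A", 19)))), 0L)
  expect_equal(nrow(index_reference_polya(c(c1 = strrep("A", 20)))), 1L)
  # T runs are minus-strand polyA
  idx_t <- index_reference_polya(c(c1 = paste0("G", strrep("T", 25), "C")))
  expect_equal(idx_t$strand, "-")
})

test_that("the synthetic reference's top three runs are the planted ones", {
  gm <- build_reference(small_config(seed = 3L))
  idx <- index_reference_polya(gm)
  expect_equal(idx$length[1:3], c(90L, 83L, 79L))
  # idempotent
  expect_identical(idx, index_reference_polya(gm))
  # strand symmetry: runs on the reverse complement mirror coordinates
  rc <- stats::setNames(revcomp(gm$seqs), names(gm$seqs))
  idx_rc <- index_reference_polya(rc)
  n <- nchar(gm$seqs[idx$chrom])
  mirrored <- data.table::data.table(chrom = idx$chrom,
                                     start = n - idx$end + 1L,
                                     end = n - idx$start + 1L,
                                     length = idx$length)
  data.table::setorder(mirrored, -length, chrom, start)
  expect_equal(idx_rc$length, mirrored$length)
  expect_setequal(paste(idx_rc$chrom, idx_rc$start, idx_rc$end),
                  paste(mirrored$chrom, mirrored$start, mirrored$end))
})

mkjunc <- function(tumour, chromA, posA, chromB, posB) {
  calls <- retroscan:::empty_junctions()
  data.table::rbindlist(c(list(calls), lapply(seq_along(posA), function(i)
    data.table::data.table(
      tumour_id = tumour[i], chromA = chromA[i], dirA = "+",
      posA = as.integer(posA[i]), chromB = chromB[i], dirB = "-",
      posB = as.integer(posB[i]), support = 3L, class = "inter_chromosomal",
      members = list("x"), junction_id = sprintf("j%03d", i),
      normal_support = 0L, panel_support = 0L, flags = "", pass = TRUE,
      partner_id = NA_character_))))
}

test_that("breakpoint clusters chain at 1 kb and apply both thresholds", {
  j <- mkjunc(c("T1", "T1", "T2", "T2", "T2"),
              rep("chr1", 5), c(0, 900, 1800, 2700, 3600) + 10000,
              paste0("chr", 2:6), seq(100, 500, 100) * 100)
  cl <- find_breakpoint_clusters(j)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$span, 3600L)
  expect_equal(cl$n_junctions, 5L)
  expect_equal(cl$n_partner_loci, 5L)
  # one tumour only: rejected
  j1 <- mkjunc(rep("T1", 5), rep("chr1", 5), c(0, 900, 1800, 2700, 3600) +
                 10000, paste0("chr", 2:6), seq(100, 500, 100) * 100)
  expect_equal(nrow(find_breakpoint_clusters(j1)), 0L)
  # four junctions: below min_junctions
  expect_equal(nrow(find_breakpoint_clusters(j[1:4])), 0L)
  # a gap over 1 kb splits the chain
  j2 <- mkjunc(c("T1", "T1", "T2", "T2", "T2"),
               rep("chr1", 5), c(0, 900, 3000, 3900, 4800) + 10000,
               paste0("chr", 2:6), seq(100, 500, 100) * 100)
  expect_equal(nrow(find_breakpoint_clusters(j2)), 0L)
})

test_that("hot-L1 proximity grouping is strand-aware with a 5 kb window", {
  hot <- data.frame(chrom = "chr1", start = 10000L, end = 16000L,
                    name = "L1hot", score = 0L, strand = "+")
  j_down <- mkjunc("T1", "chr1", 16800, "chr9", 500)   # 800 bp 3'
  expect_equal(nrow(find_hot_l1_proximal(j_down, hot, one_based = TRUE)), 1L)
  j_up <- mkjunc("T1", "chr1", 9200, "chr9", 500)      # 800 bp 5'
  expect_equal(nrow(find_hot_l1_proximal(j_up, hot, one_based = TRUE)), 0L)
  j_far <- mkjunc("T1", "chr1", 16000 + 5001, "chr9", 500)
  expect_equal(nrow(find_hot_l1_proximal(j_far, hot, one_based = TRUE)), 0L)
  # minus strand: downstream is to the genomic left
  hot_m <- transform(hot, strand = "-")
  j_left <- mkjunc("T1", "chr1", 9200, "chr9", 500)
  expect_equal(nrow(find_hot_l1_proximal(j_left, hot_m, one_based = TRUE)), 1L)
  expect_error(find_hot_l1_proximal(j_down, transform(hot, strand = "."),
                                    one_based = TRUE), "strand")
})

test_that("cluster classification follows the documented precedence", {
  ann <- list(
    elements = data.frame(id = "L1_A", family = "L1", chrom = "chr1",
                          start = 10000L, end = 16000L, strand = "+",
                          tail_len = 30L, stringsAsFactors = FALSE),
    nonref = data.frame(id = "L1_P", chrom = "chr2", pos = 50000L,
                        stringsAsFactors = FALSE),
    polya = data.table::data.table(chrom = "chr3", start = 70000L,
                                   end = 70089L, length = 90L, base = "A",
                                   strand = "+", rank = 1L))
  mkcluster <- function(chrom, start, end)
    data.table::data.table(cluster_id = "c1", chrom = chrom,
                           start = as.integer(start), end = as.integer(end),
                           span = as.integer(end - start), n_junctions = 6L,
                           n_tumours = 3L, n_partner_loci = 6L,
                           members = list(sprintf("j%02d", 1:6)))
  # 0.1-1.2 kb 3' of the reference L1: transduction with extent ~1.2 kb
  c1 <- classify_cluster(mkcluster("chr1", 16100, 17200), ann)
  expect_equal(c1$label, "transduction_reference_L1")
  expect_equal(c1$match_id, "L1_A")
  expect_equal(c1$max_transduced, 1200L)
  # within 1 kb of a non-reference donor insertion point
  c2 <- classify_cluster(mkcluster("chr2", 50100, 51000), ann)
  expect_equal(c2$label, "transduction_nonreference_L1")
  expect_equal(c2$match_id, "L1_P")
  # centred on a long polyA run
  c3 <- classify_cluster(mkcluster("chr3", 69990, 70100), ann)
  expect_equal(c3$label, "reference_element_mapping")
  # anywhere else
  c4 <- classify_cluster(mkcluster("chr3", 200000, 200400), ann)
  expect_equal(c4$label, "unclassified")
  # partition property: exactly one label each
  labs <- c(c1$label, c2$label, c3$label, c4$label)
  expect_equal(length(labs), 4L)
  expect_true(all(labs %in% c("transduction_reference_L1",
                              "transduction_nonreference_L1",
                              "reference_element_mapping", "unclassified")))
})

test_that("split mappings need both breakpoints in MEI-associated loci", {
  ann <- list(
    elements = data.frame(id = "L1_A", family = "L1", chrom = "chr1",
                          start = 10000L, end = 16000L, strand = "+",
                          tail_len = 30L, stringsAsFactors = FALSE),
    nonref = data.frame(id = character(0), chrom = character(0),
                        pos = integer(0)),
    polya = data.table::data.table(chrom = "chr3", start = 70000L,
                                   end = 70089L, length = 90L, base = "A",
                                   strand = "+", rank = 1L))
  ec <- classify_clusters(
    data.table::data.table(cluster_id = "c1", chrom = "chr1", start = 16100L,
                           end = 17200L, span = 1100L, n_junctions = 6L,
                           n_tumours = 3L, n_partner_loci = 6L,
                           members = list("j1")), ann)
  j <- mkjunc(c("T1", "T1", "T1"),
              c("chr1", "chr1", "chr5"),
              c(16500, 16500, 4000),          # flank, flank, unique
              c("chr3", "chr7", "chr6"),
              c(70050, 12345, 9999))          # polyA run, unique, unique
  out <- detect_split_mappings(j, ec, ann)
  expect_equal(out$split_mapping, c(TRUE, FALSE, FALSE))
})

test_that("polymorphism matching is nearest-within-window and strand-blind", {
  cat <- data.frame(id = c("p1", "p2"), chrom = c("chr1", "chr1"),
                    pos = c(10000L, 50000L))
  sites <- data.frame(chrom = rep("chr1", 3),
                      pos = c(10999L, 11001L, 49000L))
  m <- match_polymorphisms(sites, cat[, c("chrom", "pos", "id")])
  expect_equal(m$poly_match, c("p1", NA, "p2"))
  expect_equal(m$poly_dist, c(999L, NA, 1000L))
  # brute-force nearest-neighbour oracle on random sites
  set.seed(99)
  cat2 <- data.frame(id = sprintf("c%d", 1:30), chrom = "chr1",
                     pos = sample.int(1e6, 30))
  sites2 <- data.frame(chrom = "chr1", pos = sample.int(1e6, 100))
  m2 <- match_polymorphisms(sites2, cat2)
  for (i in seq_len(100)) {
    d <- abs(cat2$pos - sites2$pos[i])
    j <- which.min(d)
    if (d[j] <= 1000L) {
      expect_equal(m2$poly_match[i], cat2$id[j])
      expect_equal(m2$poly_dist[i], d[j])
    } else expect_true(is.na(m2$poly_match[i]))
  }
})
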