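# Junction calling: discordance classes, subclustering, filters, pairing.

fs <- list(mean = 320, sd = 40)
win <- as.integer(fs$mean + 4 * fs$sd)

test_that("discordance classes follow separation and orientation", {
  aln <- make_aln(
    chrom1 = c("chr1", "chr1", "chr1", "chr1"),
    pos1 = c(1000, 1000, 1000, 1000),
    strand1 = c("+", "+", "+", "+"),
    chrom2 = c("chr2", "chr1", "chr1", "chr1"),
    pos2 = c(5000, 1000 + fs$mean + 5 * fs$sd, 4000, 1120),
    strand2 = c("-", "-", "+", "-"))
  d <- extract_discordant(aln, fs)
  # inter-chromosomal, long-range (mean+5sd), same-strand; the fourth pair
  # is concordant and dropped
  expect_equal(nrow(d), 3L)
  expect_setequal(d$class, c("inter_chromosomal", "long_range",
                             "aberrant_orientation"))
  # duplicates and MAPQ-0 mates are excluded
  aln2 <- data.table::copy(aln)
  aln2$dup <- TRUE
  expect_equal(nrow(extract_discordant(aln2, fs)), 0L)
  aln3 <- data.table::copy(aln)
  aln3$mapq2 <- 0L
  expect_equal(nrow(extract_discordant(aln3, fs)), 0L)
})

test_that("breakpoints take the innermost read end with junction direction", {
  aln <- make_aln(chrom1 = "chr1", pos1 = 1000, strand1 = "+",
                  chrom2 = "chr2", pos2 = 5000, strand2 = "-", alen1 = 90L)
  d <- extract_discordant(aln, fs)
  expect_equal(d$posA, 1089L)  # plus strand: end of aligned segment
  expect_equal(d$dirA, "+")
  expect_equal(d$posB, 5000L)  # minus strand: start
  expect_equal(d$dirB, "-")
})

test_that("subclusters require both sides chained and same orientation", {
  p <- make_pairs(chromA = rep("chr1", 3), posA = c(100, 130, 150),
                  dirA = "+", chromB = rep("chr2", 3),
                  posB = c(900, 930, 960), dirB = "-")
  calls <- cluster_pairs(p, win, "T1")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$support, 3L)
  expect_equal(calls$posA, 150L)  # dirA "+": innermost = max
  expect_equal(calls$posB, 900L)  # dirB "-": innermost = min
  # same A side, B sides on two chromosomes -> two subclusters
  p2 <- make_pairs(chromA = rep("chr1", 3), posA = c(100, 100, 100),
                   dirA = "+", chromB = c("chr2", "chr2", "chr3"),
                   posB = c(900, 930, 900), dirB = "-")
  expect_equal(nrow(cluster_pairs(p2, win, "T1")), 2L)
})

test_that("subclustering equals the brute-force connected-components oracle", {
  set.seed(404)
  n <- 200L
  p <- make_pairs(chromA = "chr1",
                  posA = sample(c(1000, 1400, 8000, 20000), n, TRUE) +
                    sample(-300:300, n, TRUE),
                  dirA = sample(c("+", "-"), n, TRUE),
                  chromB = sample(c("chr2", "chr3"), n, TRUE),
                  posB = sample(c(500, 5000), n, TRUE) +
                    sample(-300:300, n, TRUE),
                  dirB = sample(c("+", "-"), n, TRUE))
  calls <- cluster_pairs(p, win, "T1")
  # oracle: connected components under the full pairwise predicate
  same_group <- function(i, j)
    p$chromA[i] == p$chromA[j] && p$chromB[i] == p$chromB[j] &&
    p$dirA[i] == p$dirA[j] && p$dirB[i] == p$dirB[j] &&
    abs(p$posA[i] - p$posA[j]) <= win && abs(p$posB[i] - p$posB[j]) <= win
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (same_group(i, j)) parent[find(j)] <- find(i)
  oracle_groups <- vapply(seq_len(n), find, integer(1))
  expect_equal(nrow(calls), length(unique(oracle_groups)))
  # membership must match exactly
  impl_groups <- integer(n)
  for (k in seq_len(nrow(calls)))
    impl_groups[match(calls$members[[k]], p$qname)] <- k
  expect_equal(length(unique(paste(impl_groups, oracle_groups))),
               length(unique(oracle_groups)))
  expect_equal(sum(calls$support), n)
})

test_that("normal subtraction and support thresholds set PASS correctly", {
  p <- make_pairs(chromA = rep("chr1", 3), posA = c(100, 130, 150),
                  dirA = "+", chromB = rep("chr2", 3),
                  posB = c(900, 930, 960), dirB = "-")
  calls <- cluster_pairs(p, win, "T1")
  empty <- retroscan:::empty_discordant()
  c1 <- filter_by_normals(data.table::copy(calls), empty, list(), win, 3L)
  expect_true(c1$pass)
  # one matching matched-normal pair contaminates
  npair <- make_pairs("chr1", 140, "+", "chr2", 940, "-")
  c2 <- filter_by_normals(data.table::copy(calls), npair, list(), win, 3L)
  expect_false(c2$pass)
  expect_match(c2$flags, "normal-contaminated")
  expect_equal(c2$normal_support, 1L)
  # a panel normal alone also contaminates
  c3 <- filter_by_normals(data.table::copy(calls), empty, list(npair), win, 3L)
  expect_false(c3$pass)
  expect_equal(c3$panel_support, 1L)
  # support 2: insufficient at min_support 3, PASS at 2
  p2 <- p[1:2]
  calls2 <- cluster_pairs(p2, win, "T1")
  c4 <- filter_by_normals(data.table::copy(calls2), empty, list(), win, 3L)
  expect_match(c4$flags, "insufficient-support")
  c5 <- filter_by_normals(data.table::copy(calls2), empty, list(), win, 2L)
  expect_true(c5$pass)
})

test_that("small-inversion filter applies the strict 10 kb boundary", {
  mkcall <- function(posB, chromB = "chr1", dirB = "+") {
    calls <- cluster_pairs(
      make_pairs(rep("chr1", 3), c(500, 510, 520), "+",
                 rep(chromB, 3), posB + c(0, 10, 20), dirB), win, "T")
    filter_by_normals(calls, retroscan:::empty_discordant(), list(), win, 3L)
  }
  flagged <- filter_small_inversions(mkcall(10499))  # span 9999
  kept <- filter_small_inversions(mkcall(10500))     # span exactly 10000
  inter <- filter_small_inversions(mkcall(9000, chromB = "chr2"))
  expect_equal(abs(flagged$posB - flagged$posA), 9999L)
  expect_match(flagged$flags, "small-inversion")
  expect_equal(abs(kept$posB - kept$posA), 10000L)
  expect_true(kept$pass)
  expect_true(inter$pass)
  off <- filter_small_inversions(mkcall(10499), enabled = FALSE)
  expect_true(off$pass)
})

test_that("plausible-normal-alignment filter drops homologous breakpoints", {
  shared <- random_reads(1, 150, seed = 31)
  ref <- c(chr1 = paste0(random_reads(1, 800, seed = 32), shared,
                         random_reads(1, 800, seed = 33), shared,
                         random_reads(1, 500, seed = 34)))
  calls <- cluster_pairs(
    make_pairs(rep("chr1", 3), c(850, 860, 870), "+",
               rep("chr1", 3), c(1800, 1810, 1820), "-",
               class = "long_range"), win, "T")
  calls <- filter_by_normals(calls, retroscan:::empty_discordant(), list(),
                             win, 3L)
  out <- plausible_normal_alignment_filter(data.table::copy(calls), ref)
  expect_match(out$flags, "plausible-normal-alignment")
  # 100 bp with 15 mismatches (85% identity) is kept
  a <- random_reads(1, 100, seed = 41)
  b <- a
  for (p in seq(3, 45, by = 3))
    substr(b, p, p) <- chartr("ACGT", "CGTA", substr(b, p, p))
  # breakpoint windows must not overlap each other, or the shared local
  # sequence trivially reaches 100% identity
  ref2 <- c(chr1 = paste0(random_reads(1, 700, seed = 42), a,
                          random_reads(1, 1500, seed = 43), b,
                          random_reads(1, 500, seed = 44)))
  calls2 <- cluster_pairs(
    make_pairs(rep("chr1", 3), c(750, 760, 770), "+",
               rep("chr1", 3), c(2350, 2360, 2370), "-",
               class = "long_range"), win, "T")
  calls2 <- filter_by_normals(calls2, retroscan:::empty_discordant(), list(),
                              win, 3L)
  out2 <- plausible_normal_alignment_filter(data.table::copy(calls2), ref2)
  expect_true(out2$pass)
})

test_that("sliding identity scan equals a brute-force offset/window oracle", {
  set.seed(55)
  for (i in 1:25) {
    a <- random_reads(1, 180, seed = 100 + i)
    b <- if (i %% 3 == 0) {
      # plant a shared segment with some mismatches
      s <- substr(a, 31, 150)
      nmm <- sample(0:15, 1)
      for (p in sample(120, nmm))
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      paste0(random_reads(1, 40, seed = 200 + i), s,
             random_reads(1, 30, seed = 300 + i))
    } else random_reads(1, 190, seed = 400 + i)
    impl <- cpp_best_window_identity(a, b, 100L)
    oracle <- 0
    for (off in -(nchar(b) - 100):(nchar(a) - 100)) {
      lo <- max(0, off); hi <- min(nchar(a), nchar(b) + off)
      if (hi - lo < 100) next
      av <- strsplit(substr(a, lo + 1, hi), "")[[1]]
      bv <- strsplit(substr(b, lo - off + 1, hi - off), "")[[1]]
      mm <- av != bv
      for (w in seq_len(length(mm) - 100 + 1))
        oracle <- max(oracle, 1 - sum(mm[w:(w + 99)]) / 100)
    }
    expect_equal(impl, oracle, tolerance = 1e-12)
  }
})

test_that("raising thresholds or adding panel normals never adds PASS calls", {
  set.seed(66)
  p <- make_pairs(chromA = "chr1",
                  posA = sample(c(1000, 5000, 9000), 30, TRUE) +
                    sample(-100:100, 30, TRUE),
                  dirA = "+",
                  chromB = "chr2",
                  posB = sample(c(2000, 7000), 30, TRUE) +
                    sample(-100:100, 30, TRUE),
                  dirB = "-")
  calls <- cluster_pairs(p, win, "T1")
  empty <- retroscan:::empty_discordant()
  pass_at <- function(ms, panel = list())
    sum(filter_by_normals(data.table::copy(calls), empty, panel, win,
                          ms)$pass)
  expect_true(all(diff(vapply(1:6, pass_at, integer(1))) <= 0))
  panel_pair <- p[1]
  expect_lte(pass_at(3L, list(panel_pair)), pass_at(3L))
})

test_that("reciprocal junctions of one insertion are paired", {
  # left and right junction of one insert: target sides 12 bp apart with
  # opposite directions, far sides on the donor chromosome
  calls <- data.table::rbindlist(list(
    cluster_pairs(make_pairs(rep("chr1", 3), c(5000, 5010, 5020), "+",
                             rep("chr2", 3), c(100, 110, 120), "-"),
                  win, "T1"),
    cluster_pairs(make_pairs(rep("chr1", 3), c(5032, 5040, 5052), "-",
                             rep("chr2", 3), c(900, 910, 920), "+"),
                  win, "T1")))
  calls$junction_id <- c("j1", "j2")
  out <- pair_reciprocal_junctions(data.table::copy(calls))
  expect_equal(out$partner_id, c("j2", "j1"))
  # a lone junction stays unpaired
  lone <- cluster_pairs(make_pairs(rep("chr1", 3), c(1, 2, 3), "+",
                                   rep("chr2", 3), c(1, 2, 3), "-"),
                        win, "T1")
  expect_true(is.na(pair_reciprocal_junctions(lone)$partner_id))
  # far sides further apart than window_far do not pair
  far <- data.table::copy(calls)
  far$posB[2] <- 5000L
  expect_true(all(is.na(pair_reciprocal_junctions(far,
                                                  window_far = 2000L)$partner_id)))
})

test_that("junction TSV and BEDPE are written", {
  calls <- cluster_pairs(make_pairs(rep("chr1", 3), c(100, 110, 120), "+",
                                    rep("chr2", 3), c(900, 910, 920), "-"),
                         win, "T1")
  calls <- filter_by_normals(calls, retroscan:::empty_discordant(), list(),
                             win, 3L)
  tsv <- tempfile(); bedpe <- tempfile()
  write_junctions(calls, tsv, bedpe)
  tt <- read.delim(tsv)
  expect_equal(tt$support, 3L)
  bp <- read.delim(bedpe, header = FALSE)
  expect_equal(bp$V2, tt$posA - 1L)  # BEDPE is 0-based half-open
})
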