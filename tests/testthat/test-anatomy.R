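# Insert anatomy: TSD, polyA tail, inversion, donor assignment, polyA
# addition site, and the truth round trip.

test_that("TSD detection recovers printed worked cases", {
  set.seed(10)
  # insert ATATAATAATAAT + polyA flanked both sides by CCCA, the
  # duplication of the target
  left <- paste0(random_reads(1, 60, seed = 1), "CCCA")
  ins <- paste0("ATATAATAATAAT", strrep("A", 49))
  ref_target <- paste0("CCCA", random_reads(1, 60, seed = 2))
  seqv <- paste0(left, ins, ref_target)
  tsd <- detect_tsd(seqv, nchar(left) + 1L, nchar(left) + nchar(ins),
                    ref_target)
  expect_equal(tsd$tsd_len, 4L)
  expect_equal(tsd$tsd_seq, "CCCA")
  # a 16 bp duplication
  dup <- "TAGAAGCCCAATTTCT"
  left2 <- paste0(random_reads(1, 50, seed = 3), dup)
  ins2 <- paste0(random_reads(1, 120, seed = 4), strrep("A", 30))
  ref_target2 <- paste0(dup, random_reads(1, 50, seed = 5))
  seq2 <- paste0(left2, ins2, ref_target2)
  tsd2 <- detect_tsd(seq2, nchar(left2) + 1L, nchar(left2) + nchar(ins2),
                     ref_target2)
  expect_equal(tsd2$tsd_len, 16L)
  expect_equal(tsd2$tsd_seq, dup)
  expect_error(detect_tsd(seqv, 0L, 10L, ref_target), "boundaries")
})

test_that("TSD detection equals the exhaustive oracle on 1000 planted cases", {
  set.seed(1234)
  oracle_tsd <- function(sequence, is_, ie_, ref_target, max_tsd = 30L,
                         max_del = 10L) {
    # exhaustive scan over all duplication lengths, then all deletions
    best <- 0L
    for (L in seq_len(max_tsd)) {
      if (is_ - L < 1L || ie_ + L > nchar(sequence)) break
      if (substr(sequence, is_ - L, is_ - 1L) ==
          substr(sequence, ie_ + 1L, ie_ + L) &&
          substr(sequence, is_ - L, is_ - 1L) == substr(ref_target, 1L, L))
        best <- L
    }
    if (best > 0L) return(best)
    k <- min(40L, nchar(sequence) - ie_)
    for (d in 0:max_del)
      if (substr(ref_target, d + 1L, d + k) ==
          substr(sequence, ie_ + 1L, ie_ + k)) return(-d)
    0L
  }
  n_agree <- 0L
  for (i in 1:1000) {
    tsd_true <- sample(-5:25, 1)
    target <- random_reads(1, 140, seed = 2000 + i)
    # keep the junction base distinguishable so the planted length is the
    # unique answer (as the simulator does)
    p <- 61L
    attempt <- 0L
    while (substr(target, p - 1, p - 1) == substr(target, p, p)) {
      attempt <- attempt + 1L
      target <- random_reads(1, 140, seed = 40000 + i + 1000L * attempt)
    }
    ins <- paste0(random_reads(1, sample(10:60, 1), seed = 3000 + i),
                  strrep("A", sample(25:50, 1)))
    if (tsd_true >= 0) {
      left <- substr(target, 1, p + tsd_true - 1L)
      right <- substr(target, p, 140)
    } else {
      left <- substr(target, 1, p - 1L)
      right <- substr(target, p - tsd_true, 140)
    }
    seqv <- paste0(left, ins, right)
    ref_target <- substr(target, p, 140)
    got <- detect_tsd(seqv, nchar(left) + 1L, nchar(left) + nchar(ins),
                      ref_target)$tsd_len
    ora <- oracle_tsd(seqv, nchar(left) + 1L, nchar(left) + nchar(ins),
                      ref_target)
    expect_equal(got, ora)
    if (got == tsd_true) n_agree <- n_agree + 1L
  }
  # the oracle equals the implementation on all cases; coincidental flank
  # self-similarity may legitimately lengthen a few detected TSDs
  expect_gte(n_agree, 950L)
})

test_that("polyA tail measurement follows the anchored slippage rule", {
  expect_equal(measure_polya_tail(paste0(random_reads(1, 30, seed = 9), "G",
                                         strrep("A", 37))), 37L)
  # one non-A absorbed when at least nine As continue the tail past it
  with_slip <- paste0(random_reads(1, 20, seed = 8), "C", strrep("A", 15),
                      "G", strrep("A", 10))
  expect_equal(measure_polya_tail(with_slip), 26L)
  # a non-A with fewer than nine As beyond it stops the tail
  stopped <- paste0("TAAT", strrep("A", 49))
  expect_equal(measure_polya_tail(stopped), 49L)
  expect_equal(measure_polya_tail(paste0("ATATAATAATAAT", strrep("A", 49))),
               49L)
  expect_equal(measure_polya_tail("ACGTACGTACGT"), 0L)
  expect_equal(measure_polya_tail(""), 0L)
  expect_equal(measure_polya_tail(strrep("A", 40)), 40L)
})

test_that("5' inversion detection reports prefix length and donor gap", {
  donor <- random_reads(1, 2000, seed = 21)
  main <- substr(donor, 500, 1200)
  prefix <- revcomp(substr(donor, 500 - 54 - 17, 500 - 54 - 1))  # 17 bp, 54 gap
  body <- paste0(prefix, main)
  inv <- detect_inversion(body, donor)
  expect_equal(inv$status, "partial_5prime")
  expect_equal(inv$inv_len, 17L)
  expect_equal(inv$inv_gap, 54L)
  # non-inverted insert
  expect_equal(detect_inversion(main, donor)$status, "none")
  # fully inverted insert
  expect_equal(detect_inversion(revcomp(main), donor)$status, "whole_insert")
})

test_that("donor assignment distinguishes flank-only, mixed and twin copies", {
  gm <- build_reference(small_config(seed = 47L))
  dl <- donor_library(gm)
  d1 <- dl[[1]]
  # flank-only insert: L1 content 0, transduced interval recovered
  body_flank <- substr(d1$flank, 1, 400)
  a1 <- assign_donor(body_flank, dl)
  expect_equal(a1$donor, d1$id)
  expect_true(a1$assigned)
  expect_equal(a1$l1_fraction, 0)
  expect_equal(a1$transduced, c(1L, 400L))
  # 69 bp of element 3' end plus flank
  body_mix <- paste0(substr(d1$element, nchar(d1$element) - 68,
                            nchar(d1$element)), substr(d1$flank, 1, 300))
  a2 <- assign_donor(body_mix, dl)
  expect_equal(a2$donor, d1$id)
  expect_equal(a2$transduced[2], 300L)
  expect_equal(a2$l1_fraction, 69 / nchar(body_mix), tolerance = 0.02)
  # element-only insert from a specific copy: diagnostic bases break the tie
  l1s <- dl[vapply(dl, function(d) d$in_reference, logical(1))]
  l1s <- l1s[vapply(l1s, function(d) nchar(d$element) > 2000, logical(1))]
  d2 <- l1s[[2]]
  # a segment containing one of d2's diagnostic bases
  off <- d2$diagnostic$offset[2]
  body_el <- substr(d2$element, max(1, off - 200), min(nchar(d2$element),
                                                       off + 200))
  a3 <- assign_donor(body_el, dl)
  expect_equal(a3$donor, d2$id)
  expect_null(a3$transduced)
  # unassignable sequence is flagged
  a4 <- assign_donor(random_reads(1, 300, seed = 48), dl)
  expect_false(a4$assigned)
})

test_that("polyA addition sites aggregate per donor across inserts", {
  gm <- build_reference(small_config(seed = 53L))
  dl <- donor_library(gm)
  d <- dl[[1]]
  offs <- d$polya_site_offsets
  sites <- vapply(offs, function(s)
    polya_addition_site(d, c(1L, s)), integer(1))
  donor_rec <- Filter(function(x) x$id == d$id, gm$donors)[[1]]
  expect_setequal(sites, donor_rec$polya_sites)
  # element-only insert reports the element 3' end
  el_site <- polya_addition_site(d, NULL, element_only = TRUE)
  if (d$strand == "+") {
    expect_equal(el_site, donor_rec$end - donor_rec$tail_len)
  } else {
    expect_equal(el_site, donor_rec$start + donor_rec$tail_len)
  }
  # polyA-only insert has no defined site
  expect_true(is.na(polya_addition_site(d, NULL, element_only = FALSE)))
})

test_that("anatomy round-trips the simulation truth", {
  cfg <- small_config(seed = 59L)
  gm <- build_reference(cfg)
  sim <- simulate_tumour(gm, cfg, "T1", n_inserts = 40L)
  an <- anatomize_truth(gm, sim$truth)
  tr <- sim$truth
  expect_equal(nrow(an), nrow(tr))
  # conservation on every call
  expect_equal(an$non_polya_len + an$tail_len, an$insert_len)
  # TSD length exactly
  expect_equal(an$tsd_len, tr$tsd)
  # orientation exactly
  expect_equal(an$orientation, tr$orientation)
  # tail length within 2 bp (flank bases adjoining the tail may be A)
  expect_true(all(abs(an$tail_len - tr$tail_len) <= 2L))
  # inversion presence
  expect_equal(an$inversion == "partial_5prime", !is.na(tr$inv_len))
  detected <- !is.na(tr$inv_len)
  expect_true(all(abs(an$inv_len[detected] - tr$inv_len[detected]) <= 2L))
  # donor assignment and transduced extent within 2 bp; element-only
  # inserts from copies differing only at uncovered diagnostic bases are
  # inherently ambiguous, so exact donor identity is asserted where the
  # insert carries (unique) transduced sequence
  nonempty <- tr$retained3p + tr$transduced >= 30L
  expect_true(all(an$assigned[nonempty]))
  transd30 <- tr$transduced >= 30L
  expect_equal(an$donor[transd30], tr$donor[transd30])
  expect_true(all(abs(an$transduced_extent[nonempty] -
                        tr$transduced[nonempty]) <= 2L))
  # polyA addition sites match the truth for transduced inserts
  transd <- nonempty & tr$transduced > 0L
  expect_true(all(abs(an$polya_site[transd] - tr$polya_site[transd]) <= 2L))
})
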