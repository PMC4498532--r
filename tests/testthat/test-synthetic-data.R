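# Simulator: reference construction, tumour genomes, reads and truth IO.

test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(p_transduction = 1.5), "probabilities")
  expect_error(sim_config(polya_tail_range = c(15, 60)), "polya_tail_range")
  expect_error(sim_config(read_length = 400, fragment_mean = 320),
               "read_length")
  expect_error(sim_config(coverage = 0), "coverage")
  cfg <- small_config()
  expect_s3_class(cfg, "retroscan_config")
  expect_equal(sum(cfg$tsd_weights), 1, tolerance = 1e-12)
})

test_that("config round-trips through YAML", {
  cfg <- small_config(seed = 99L)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$seed, 99L)
  expect_equal(cfg2$planted_polya_lengths, cfg$planted_polya_lengths)
  expect_equal(cfg2$fragment_mean, cfg$fragment_mean)
})

test_that("reference carries exactly the planted polyA runs as longest runs", {
  gm <- build_reference(small_config())
  idx <- index_reference_polya(gm, min_run = 50L)
  expect_equal(idx$length[1:3], c(90L, 83L, 79L))
  # planted runs are plus-strand pure A
  expect_true(all(idx$strand[1:3] == "+"))
})

test_that("a featureless reference has an empty element annotation", {
  cfg <- small_config(n_reference_L1 = 0L, n_nonreference_L1 = 0L,
                      n_alu = 0L, planted_polya_lengths = integer(0),
                      n_genes = 0L)
  gm <- build_reference(cfg)
  expect_null(gm$elements)
  dir <- tempfile(); dir.create(dir)
  write_reference(gm, dir)
  expect_equal(length(readLines(file.path(dir, "elements.bed"))), 0L)
})

test_that("genome too short for the requested features errors with the deficit", {
  expect_error(build_reference(small_config(genome_length = 5e4)),
               "genome too short")
})

test_that("every donor's transducible flank occurs exactly once genome-wide", {
  gm <- build_reference(small_config(seed = 7L))
  dl <- donor_library(gm)
  fasta <- paste(unlist(gm$seqs), collapse = "N")
  for (d in dl) {
    probe <- if (d$strand == "-") revcomp(d$flank) else d$flank
    hits <- gregexpr(probe, fasta, fixed = TRUE)[[1]]
    expect_equal(sum(hits > 0), 1L, info = d$id)
    # and the reverse complement does not occur
    expect_equal(gregexpr(revcomp(probe), fasta, fixed = TRUE)[[1]][1], -1L)
  }
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_config(seed = 5L)
  g1 <- build_reference(cfg); g2 <- build_reference(cfg)
  expect_identical(g1$seqs, g2$seqs)
  s1 <- simulate_tumour(g1, cfg, "T1"); s2 <- simulate_tumour(g2, cfg, "T1")
  expect_identical(s1$tumour, s2$tumour)
  expect_identical(s1$truth, s2$truth)
  r1 <- generate_read_pairs(s1$tumour, cfg, "T1")
  r2 <- generate_read_pairs(s2$tumour, cfg, "T1")
  expect_identical(r1, r2)
  f1 <- tempfile(); f2 <- tempfile()
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(s1$tumour), f1)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(s2$tumour), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("tumour genome length obeys conservation and truth matches edits", {
  cfg <- small_config(seed = 3L)
  gm <- build_reference(cfg)
  sim <- simulate_tumour(gm, cfg, "T1")
  gain <- sum(sim$truth$insert_len + sim$truth$tsd)
  expect_equal(sum(nchar(sim$tumour)), sum(nchar(sim$normal)) + gain)
  # the planted insert sequence is recoverable verbatim at each target
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    expect_true(grepl(tr$insert_seq, sim$tumour[[tr$chrom]], fixed = TRUE))
  }
  # every insert ends (on its own strand) in >= configured minimum polyA
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    oriented <- if (tr$orientation == "-") revcomp(tr$insert_seq) else
      tr$insert_seq
    n <- nchar(oriented)
    tail <- substr(oriented, n - cfg$polya_tail_range[1] + 1L, n)
    expect_equal(tail, strrep("A", cfg$polya_tail_range[1]))
  }
})

test_that("matched normal shares no somatic insert with the tumour", {
  cfg <- small_config(seed = 13L)
  gm <- build_reference(cfg)
  sim <- simulate_tumour(gm, cfg, "T1")
  # the junction string (target left flank + insert start) is unique to the
  # tumour; the insert body alone may legitimately occur in the germline
  # (an element-plus-tail insert is a copy of its donor locus)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    left_end <- if (tr$tsd > 0) tr$pos + tr$tsd - 1L else tr$pos - 1L
    junction <- paste0(substr(gm$seqs[[tr$chrom]], left_end - 29L, left_end),
                       substr(tr$insert_seq, 1L, 30L))
    expect_true(grepl(junction, sim$tumour[[tr$chrom]], fixed = TRUE))
    expect_false(grepl(junction, sim$normal[[tr$chrom]], fixed = TRUE))
  }
  # but carried non-reference donors are present in both genomes
  if (!is.null(sim$events)) {
    for (i in seq_len(nrow(sim$events))) {
      ev <- sim$events[i, ]
      expect_true(grepl(ev$insert_seq, sim$normal[[ev$chrom]], fixed = TRUE))
      expect_true(grepl(ev$insert_seq, sim$tumour[[ev$chrom]], fixed = TRUE))
    }
  }
})

test_that("suppressing transduction and truncation leaves polyA-only inserts", {
  cfg <- small_config(seed = 21L, p_transduction = 0, truncation_mean = 0,
                      p_inversion = 0)
  gm <- build_reference(cfg)
  sim <- simulate_tumour(gm, cfg, "T1", n_inserts = 12L)
  polya_only <- sim$truth$retained3p == 0L
  expect_true(mean(polya_only) > 0.9)  # geometric(mean 0) is almost surely 0
  ins <- sim$truth$insert_seq[polya_only & sim$truth$orientation == "+"]
  expect_true(all(grepl("^A+$", ins)))
})

test_that("a zero-length TSD is a pure insertion without duplication", {
  # constructed directly through the editing primitive
  seq <- "ACGTACGTACGTACGTACGT"
  out <- retroscan:::apply_insertions(seq, pos = 9L, tsd = 0L,
                                      insert_seq = "TTTT")
  expect_equal(out, paste0(substr(seq, 1, 8), "TTTT", substr(seq, 9, 20)))
  out2 <- retroscan:::apply_insertions(seq, pos = 9L, tsd = 3L,
                                       insert_seq = "TTTT")
  expect_equal(out2, paste0(substr(seq, 1, 11), "TTTT", substr(seq, 9, 20)))
  out3 <- retroscan:::apply_insertions(seq, pos = 9L, tsd = -2L,
                                       insert_seq = "TTTT")
  expect_equal(out3, paste0(substr(seq, 1, 8), "TTTT", substr(seq, 11, 20)))
})

test_that("observed inversion fraction sits in the exact binomial 99% CI", {
  cfg <- small_config(seed = 17L, genome_length = 2e6, n_chromosomes = 2L)
  gm <- build_reference(cfg)
  sim <- simulate_tumour(gm, cfg, "T1", n_inserts = 200L)
  # twin priming needs enough pre-inversion body (>= 40 bp with the default
  # inversion length range), so the binomial check conditions on eligible
  # inserts
  eligible <- sim$truth$retained3p + sim$truth$transduced >= 40L
  n <- sum(eligible)
  n_inv <- sum(!is.na(sim$truth$inv_len[eligible]))
  expect_equal(sum(!is.na(sim$truth$inv_len[!eligible])), 0L)
  lo <- stats::qbinom(0.005, n, cfg$p_inversion)
  hi <- stats::qbinom(0.995, n, cfg$p_inversion)
  expect_gte(n_inv, lo)
  expect_lte(n_inv, hi)
})

test_that("read generation respects coverage, purity and fragment law", {
  cfg <- small_config(seed = 9L, base_error_rate = 0, lowq_read_rate = 0)
  gm <- build_reference(cfg)
  reads <- generate_read_pairs(gm$seqs, cfg, "S")
  total_bases <- 2 * cfg$read_length * nrow(reads)
  expect_lt(abs(total_bases - cfg$coverage * sum(nchar(gm$seqs))) /
              (cfg$coverage * sum(nchar(gm$seqs))), 0.01)
  # error-free reads are exact substrings (mate2 reverse-complemented)
  idx <- sample(nrow(reads), 50)
  for (i in idx) {
    cs <- gm$seqs[[reads$chrom[i]]]
    expect_identical(substr(cs, reads$frag_start[i],
                            reads$frag_start[i] + cfg$read_length - 1L),
                     reads$seq1[i])
    expect_identical(revcomp(reads$seq2[i]),
                     substr(cs, reads$frag_start[i] + reads$frag_len[i] -
                              cfg$read_length,
                            reads$frag_start[i] + reads$frag_len[i] - 1L))
  }
  # fragment lengths recomputed from the truth-tagged read names
  flen <- as.integer(vapply(strsplit(reads$qname, ":"), `[[`, character(1), 4))
  expect_identical(flen, reads$frag_len)
  expect_lt(abs(mean(flen) - cfg$fragment_mean),
            3 * cfg$fragment_sd / sqrt(length(flen)))
})

test_that("FASTQ round-trips reads and qualities", {
  cfg <- small_config(seed = 2L, coverage = 2)
  gm <- build_reference(cfg)
  reads <- generate_read_pairs(gm$seqs, cfg, "S")[1:100]
  prefix <- tempfile()
  write_fastq(reads, prefix)
  back <- read_fastq(prefix)
  expect_identical(back$qname, reads$qname)
  expect_identical(back$seq1, reads$seq1)
  expect_identical(back$qual2, reads$qual2)
})

test_that("truth serialisation round-trips exactly and BED encodes deletions", {
  cfg <- small_config(seed = 31L)
  gm <- build_reference(cfg)
  sim <- simulate_tumour(gm, cfg, "T1")
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_truth(sim$truth, tsv, bed)
  back <- read_truth(tsv)
  expect_equal(as.data.frame(back), as.data.frame(sim$truth))
  bed_df <- retroscan:::read_bed(bed)
  w <- bed_df$end - bed_df$start
  expect_equal(w, abs(sim$truth$tsd))
  # empty truth: header-only TSV
  tsv0 <- tempfile()
  write_truth(sim$truth[0, ], tsv0)
  expect_equal(length(readLines(tsv0)), 1L)
  expect_equal(nrow(read_truth(tsv0)), 0L)
})
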