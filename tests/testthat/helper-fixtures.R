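# Shared fixtures: small configurations and hand-built alignment tables.

small_config <- function(seed = 42L, ...) {
  defaults <- list(seed = seed, genome_length = 3e5, n_chromosomes = 2L,
                   n_reference_L1 = 2L, n_nonreference_L1 = 1L, n_alu = 2L,
                   coverage = 25, n_tumours = 1L, n_panel_normals = 1L,
                   inserts_per_tumour = list(mu = 8, size = 10), n_genes = 3L)
  override <- list(...)
  do.call(sim_config, utils::modifyList(defaults, override))
}

# minimal alignment_set row(s) built by hand
make_aln <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                     mapq1 = 60L, mapq2 = 60L, alen1 = 100L, alen2 = 100L,
                     qname = NULL, seq = strrep("A", 100),
                     qual = strrep("I", 100), dup = FALSE, proper = FALSE,
                     isize = NA_integer_) {
  n <- length(chrom1)
  if (is.null(qname)) qname <- sprintf("r%03d", seq_len(n))
  aln <- data.table::data.table(
    qname = qname, chrom1 = chrom1, pos1 = as.integer(pos1),
    strand1 = strand1, mapq1 = as.integer(mapq1), clipl1 = 0L, clipr1 = 0L,
    alen1 = as.integer(alen1), score1 = 100L,
    chrom2 = chrom2, pos2 = as.integer(pos2), strand2 = strand2,
    mapq2 = as.integer(mapq2), clipl2 = 0L, clipr2 = 0L,
    alen2 = as.integer(alen2), score2 = 100L,
    seq1 = seq, qual1 = qual, seq2 = seq, qual2 = qual,
    dup = dup, isize = as.integer(isize), proper = proper)
  data.table::setattr(aln, "class", c("alignment_set", class(aln)))
  aln
}

# discordant-pair table built by hand (already canonicalised)
make_pairs <- function(chromA, posA, dirA, chromB, posB, dirB,
                       class = "inter_chromosomal") {
  data.table::data.table(
    qname = sprintf("q%03d", seq_along(posA)),
    chromA = chromA, posA = as.integer(posA), dirA = dirA,
    chromB = chromB, posB = as.integer(posB), dirB = dirB, class = class)
}

random_reads <- function(n, len = 100L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
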