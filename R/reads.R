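# Paired-end read generation. Fragments are Normal(fragment_mean,
# fragment_sd) truncated at the read length; two inner-facing reads per
# fragment; substitution errors at base_error_rate with the error positions
# marked by low quality symbols. Read names encode the fragment origin so
# that downstream results can be checked against the truth.

QUAL_HIGH <- "I"   # Phred 40
QUAL_LOW <- "#"    # minimum of the encoding scale

inject_errors <- function(seqs, quals, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(list(seqs = seqs, quals = quals))
  L <- nchar(seqs[1])
  nerr <- stats::rbinom(length(seqs), L, rate)
  idx <- which(nerr > 0L)
  one <- idx[nerr[idx] == 1L]
  if (length(one)) {
    p <- sample.int(L, length(one), replace = TRUE)
    old <- substr(seqs[one], p, p)
    # deterministic substitution cycle A->C->G->T->A keeps this vectorised;
    # which base an error becomes is immaterial downstream
    new <- chartr("ACGT", "CGTA", old)
    substr(seqs[one], p, p) <- new
    substr(quals[one], p, p) <- QUAL_LOW
  }
  multi <- idx[nerr[idx] > 1L]
  for (i in multi) {
    p <- sample.int(L, nerr[i])
    for (pp in p) {
      substr(seqs[i], pp, pp) <- chartr("ACGT", "CGTA", substr(seqs[i], pp, pp))
      substr(quals[i], pp, pp) <- QUAL_LOW
    }
  }
  list(seqs = seqs, quals = quals)
}

#' Generate paired-end reads from a set of chromosome sequences
#'
#' @param seqs named character vector of chromosome sequences (a tumour or
#'   normal genome).
#' @param config the [sim_config()]; uses read_length, fragment_mean/sd,
#'   coverage, base_error_rate, lowq_read_rate.
#' @param sample_id sample label, embedded in read names
#'   (`sample:chrom:fragstart:fraglen:i`).
#' @param seed optional integer; defaults to a stream derived from the config
#'   seed and the sample id.
#' @return a `data.table` with columns qname, seq1, qual1, seq2, qual2 plus
#'   origin columns chrom, frag_start, frag_len.
#' @export
generate_read_pairs <- function(seqs, config, sample_id,
                                seed = child_seed(config$seed, "reads", sample_id)) {
  stopifnot(config$coverage > 0)
  set.seed(seed)
  L <- config$read_length
  out <- vector("list", length(seqs))
  for (ci in seq_along(seqs)) {
    cn <- names(seqs)[ci]
    slen <- nchar(seqs[[ci]])
    nfrag <- as.integer(round(slen * config$coverage / (2 * L)))
    if (nfrag == 0L) next
    flen <- as.integer(round(stats::rnorm(nfrag, config$fragment_mean,
                                          config$fragment_sd)))
    flen <- pmin(pmax(flen, L), slen)
    fstart <- as.integer(floor(stats::runif(nfrag) * (slen - flen + 1))) + 1L
    seq1 <- substring(seqs[[ci]], fstart, fstart + L - 1L)
    seq2 <- revcomp(substring(seqs[[ci]], fstart + flen - L, fstart + flen - 1L))
    qual <- strrep(QUAL_HIGH, L)
    e1 <- inject_errors(seq1, rep(qual, nfrag), config$base_error_rate)
    e2 <- inject_errors(seq2, rep(qual, nfrag), config$base_error_rate)
    qual1 <- e1$quals; qual2 <- e2$quals
    if (config$lowq_read_rate > 0) {
      bad1 <- stats::runif(nfrag) < config$lowq_read_rate
      bad2 <- stats::runif(nfrag) < config$lowq_read_rate
      qual1[bad1] <- strrep(QUAL_LOW, L)
      qual2[bad2] <- strrep(QUAL_LOW, L)
    }
    out[[ci]] <- data.table::data.table(
      qname = sprintf("%s:%s:%d:%d:%d", sample_id, cn, fstart, flen,
                      seq_len(nfrag)),
      seq1 = e1$seqs, qual1 = qual1, seq2 = e2$seqs, qual2 = qual2,
      chrom = cn, frag_start = fstart, frag_len = flen)
  }
  data.table::rbindlist(out)
}

#' Write paired reads as FASTQ
#'
#' @param reads table from [generate_read_pairs()].
#' @param prefix output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return invisibly, the two paths.
#' @export
write_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    ss <- Biostrings::DNAStringSet(reads[[paste0("seq", m)]])
    names(ss) <- paste0(reads$qname, "/", m)
    q <- Biostrings::BStringSet(reads[[paste0("qual", m)]])
    qs <- Biostrings::QualityScaledDNAStringSet(
      ss, Biostrings::PhredQuality(q))
    Biostrings::writeQualityScaledXStringSet(qs, paths[m])
  }
  invisible(paths)
}

#' Read a FASTQ pair written by [write_fastq()]
#' @param prefix prefix used at write time.
#' @return a `data.table` with qname, seq1, qual1, seq2, qual2.
#' @export
read_fastq <- function(prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(paths[1]))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(paths[2]))
  data.table::data.table(
    qname = sub("/1$", "", names(r1)),
    seq1 = as.character(r1), qual1 = as.character(Biostrings::quality(r1)),
    seq2 = as.character(r2), qual2 = as.character(Biostrings::quality(r2)))
}
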