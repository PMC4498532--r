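# Simplified deterministic seed-and-extend aligner over an exact k-mer
# index, with ungapped extension and soft-clipped tails. Two dialects
# reproduce characteristic aligner behaviours on polyA-rich reads:
#
#  * "strict"   (BWA-like): a placement needs >= 30 matching bases outside
#    long homopolymer runs, so reads that are mostly polyA stay unmapped.
#  * "trimming" (Novoalign-like): placements may additionally be anchored by
#    a >= 20 bp homopolymer run matched onto a reference polyA run with as
#    few as 4 matching flanking bases, the rest of the read soft-clipped.
#
# MAPQ = min(60, 6 * (best score - second best)) and 0 on ties, so unique
# placements clear a MAPQ >= 30 gate while ambiguous ones do not.

#' Align paired reads to a reference
#'
#' @param reads table from [generate_read_pairs()] (or [read_fastq()]).
#' @param genome a `genome_model`, or a named character vector of
#'   chromosome sequences.
#' @param dialect `"strict"` or `"trimming"`.
#' @param k exact seed length (default 20); reads shorter than `k` are
#'   reported unmapped.
#' @param fragment_mean,fragment_sd expected fragment law used for the
#'   proper-pair flag (inner-facing mates within `mean + 4 sd`). Defaults
#'   come from the genome's config when available.
#' @param min_anchor matching-base requirement (see dialect rules).
#' @param seed_step,max_occ seeding stride and repeat-occurrence cap.
#' @return an `alignment_set`: a `data.table` with one row per pair holding
#'   both mates' placements (chrom, 1-based pos, strand, mapq, soft-clip
#'   lengths, aligned length, score), the pair's insert size, proper-pair
#'   and duplicate flags, and the read sequences/qualities.
#' @export
align_pairs <- function(reads, genome, dialect = c("strict", "trimming"),
                        k = 20L,
                        fragment_mean = NULL, fragment_sd = NULL,
                        min_anchor = 30L, seed_step = 15L, max_occ = 64L) {
  dialect <- match.arg(dialect)
  seqs <- if (inherits(genome, "genome_model")) genome$seqs else genome
  if (is.null(fragment_mean))
    fragment_mean <- if (inherits(genome, "genome_model"))
      genome$config$fragment_mean else 320
  if (is.null(fragment_sd))
    fragment_sd <- if (inherits(genome, "genome_model"))
      genome$config$fragment_sd else 40
  strict <- dialect == "strict"
  a1 <- cpp_align_reads(unname(seqs), reads$seq1, k, seed_step, max_occ,
                        strict, min_anchor, 20L, 4L)
  a2 <- cpp_align_reads(unname(seqs), reads$seq2, k, seed_step, max_occ,
                        strict, min_anchor, 20L, 4L)
  cn <- names(seqs)
  aln <- data.table::data.table(
    qname = reads$qname,
    chrom1 = cn[a1$chrom], pos1 = a1$pos,
    strand1 = c("+", "-")[a1$strand + 1L], mapq1 = a1$mapq,
    clipl1 = a1$clip_left, clipr1 = a1$clip_right, alen1 = a1$aln_len,
    score1 = a1$score,
    chrom2 = cn[a2$chrom], pos2 = a2$pos,
    strand2 = c("+", "-")[a2$strand + 1L], mapq2 = a2$mapq,
    clipl2 = a2$clip_left, clipr2 = a2$clip_right, alen2 = a2$aln_len,
    score2 = a2$score,
    seq1 = reads$seq1, qual1 = reads$qual1,
    seq2 = reads$seq2, qual2 = reads$qual2)
  aln[, dup := FALSE]
  both <- !is.na(aln$chrom1) & !is.na(aln$chrom2)
  same <- both & aln$chrom1 == aln$chrom2 & aln$strand1 != aln$strand2
  lo <- ifelse(aln$strand1 == "+", aln$pos1, aln$pos2)
  hi_end <- ifelse(aln$strand1 == "+", aln$pos2 + aln$alen2,
                   aln$pos1 + aln$alen1)
  isize <- hi_end - lo
  inner <- same & ((aln$strand1 == "+" & aln$pos1 <= aln$pos2 + aln$alen2) |
                   (aln$strand2 == "+" & aln$pos2 <= aln$pos1 + aln$alen1))
  aln[, isize := ifelse(same, isize, NA_integer_)]
  aln[, proper := inner & !is.na(isize) & isize > 0 &
        isize <= fragment_mean + 4 * fragment_sd]
  data.table::setattr(aln, "class",
                      c("alignment_set", class(aln)))
  data.table::setattr(aln, "dialect", dialect)
  aln
}

#' @export
print.alignment_set <- function(x, ...) {
  n <- nrow(x)
  m1 <- sum(!is.na(x$chrom1)); m2 <- sum(!is.na(x$chrom2))
  cat(sprintf("alignment_set (%s dialect): %d pairs; mate1 mapped %.1f%%, mate2 %.1f%%, proper %.1f%%, dup %d\n",
              attr(x, "dialect") %||% "?", n, 100 * m1 / max(n, 1),
              100 * m2 / max(n, 1), 100 * sum(x$proper) / max(n, 1),
              sum(x$dup)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate fragment statistics from concordant pairs
#'
#' @param aln an `alignment_set`.
#' @param cap upper bound on plausible insert sizes considered (guards the
#'   estimate against structural-variant pairs).
#' @return list with `mean` and `sd`.
#' @export
estimate_fragment_stats <- function(aln, cap = 5000L) {
  is_conc <- !is.na(aln$isize) & aln$isize > 0 & aln$isize <= cap
  sizes <- aln$isize[is_conc]
  if (length(sizes) < 2L)
    stop("no concordant pairs to estimate fragment statistics from; supply them")
  list(mean = mean(sizes), sd = stats::sd(sizes))
}

# summed phred quality of both mates (duplicate survivor choice)
pair_quality <- function(aln) {
  q <- paste0(aln$qual1, aln$qual2)
  vapply(q, function(s) sum(utf8ToInt(s)) - 33L * nchar(s), numeric(1),
         USE.NAMES = FALSE)
}

#' Remove duplicate read pairs
#'
#' Exact mode drops pairs sharing both mates' (chrom, pos, strand), keeping
#' the pair with the highest summed base quality. Near mode additionally
#' collapses pairs whose one end differs by at most `near_bp` (default 2)
#' while the other end is identical, emulating PCR duplicates whose primer
#' lacked a terminal base or two.
#'
#' @param aln an `alignment_set`.
#' @param mode `"exact"` or `"near"`.
#' @param near_bp positional tolerance of the near mode.
#' @return the `alignment_set` with non-survivors removed.
#' @export
remove_duplicates <- function(aln, mode = c("exact", "near"), near_bp = 2L) {
  mode <- match.arg(mode)
  if (nrow(aln) == 0L) return(aln)
  key1 <- paste(aln$chrom1, aln$pos1, aln$strand1)
  key2 <- paste(aln$chrom2, aln$pos2, aln$strand2)
  mapped <- !is.na(aln$chrom1) & !is.na(aln$chrom2)
  qual <- pair_quality(aln)
  grp <- rep(NA_integer_, nrow(aln))
  grp[mapped] <- match(paste(key1[mapped], key2[mapped]),
                       unique(paste(key1[mapped], key2[mapped])))
  if (mode == "near") {
    # single-linkage within pairs sharing one identical end: chain the other
    # end's position at <= near_bp
    for (side in 1:2) {
      fixed <- if (side == 1) key1 else key2
      vpos <- if (side == 1) aln$pos2 else aln$pos1
      vkey <- if (side == 1) paste(aln$chrom2, aln$strand2)
              else paste(aln$chrom1, aln$strand1)
      gk <- paste(fixed, vkey)
      for (g in unique(gk[mapped])) {
        sel <- which(mapped & gk == g)
        if (length(sel) < 2L) next
        cl <- chain_positions(vpos[sel], near_bp)
        for (cc in unique(cl)) {
          members <- sel[cl == cc]
          grp[members] <- min(grp[members])
        }
      }
    }
  }
  keep <- rep(TRUE, nrow(aln))
  for (g in unique(grp[!is.na(grp)])) {
    members <- which(!is.na(grp) & grp == g)
    if (length(members) > 1L)
      keep[members[-which.max(qual[members])]] <- FALSE
  }
  aln[keep]
}

# ---------------------------------------------------------------------------
# SAM text IO. Rsamtools only reads binary BAM, and no installed package
# writes SAM text from in-memory records, so the (line-oriented, tab
# separated) format is written and parsed here directly.
# ---------------------------------------------------------------------------

sam_flag <- function(mate, mapped, mate_mapped, strand, mate_strand, proper,
                     dup) {
  f <- 1L +                       # paired
    ifelse(proper & mapped & mate_mapped, 2L, 0L) +
    ifelse(mapped, 0L, 4L) + ifelse(mate_mapped, 0L, 8L) +
    ifelse(mapped & strand == "-", 16L, 0L) +
    ifelse(mate_mapped & mate_strand == "-", 32L, 0L) +
    ifelse(mate == 1L, 64L, 128L) + ifelse(dup, 1024L, 0L)
  f
}

cigar_string <- function(clipl, alen, clipr, mapped) {
  ifelse(!mapped, "*",
         paste0(ifelse(clipl > 0, paste0(clipl, "S"), ""),
                alen, "M",
                ifelse(clipr > 0, paste0(clipr, "S"), "")))
}

#' Write an alignment set as SAM text
#'
#' Standard @HD/@SQ headers, FLAG bits, 1-based POS, soft-clips as S
#' operations. Minus-strand records store the reverse-complemented sequence,
#' as SAM requires.
#'
#' @param aln an `alignment_set`.
#' @param genome the `genome_model` (or named sequences) aligned against.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sam <- function(aln, genome, path) {
  seqs <- if (inherits(genome, "genome_model")) genome$seqs else genome
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs)))
  fmt_mate <- function(mate) {
    other <- 3L - mate
    g <- function(col, m) aln[[paste0(col, m)]]
    mapped <- !is.na(g("chrom", mate))
    mate_mapped <- !is.na(g("chrom", other))
    flag <- sam_flag(mate, mapped, mate_mapped, g("strand", mate),
                     g("strand", other), aln$proper, aln$dup)
    seq <- g("seq", mate); qual <- g("qual", mate)
    neg <- mapped & g("strand", mate) == "-"
    if (any(neg)) {
      seq[neg] <- revcomp(seq[neg])
      qual[neg] <- vapply(strsplit(qual[neg], ""), function(x)
        paste(rev(x), collapse = ""), character(1))
    }
    rnext <- ifelse(!mate_mapped, "*",
                    ifelse(mapped & g("chrom", other) == g("chrom", mate),
                           "=", g("chrom", other)))
    paste(aln$qname, flag,
          ifelse(mapped, g("chrom", mate), "*"),
          ifelse(mapped, g("pos", mate), 0L),
          ifelse(mapped, g("mapq", mate), 0L),
          cigar_string(g("clipl", mate), g("alen", mate), g("clipr", mate),
                       mapped),
          rnext, ifelse(mate_mapped, g("pos", other), 0L),
          ifelse(aln$proper, ifelse(g("strand", mate) == "+", 1L, -1L) *
                   data.table::fifelse(is.na(aln$isize), 0L,
                                       as.integer(aln$isize)), 0L),
          seq, qual, sep = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(aln) > 0) {
    body <- character(2L * nrow(aln))
    body[seq(1L, length(body), by = 2L)] <- fmt_mate(1L)
    body[seq(2L, length(body), by = 2L)] <- fmt_mate(2L)
    writeLines(body, con)
  }
  invisible(path)
}

#' Read SAM text written by [write_sam()] back into an alignment set
#' @param path SAM file path.
#' @return an `alignment_set`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L) stop("SAM file has no alignment records")
  f <- data.table::fread(text = body, sep = "\t", header = FALSE,
                         colClasses = list(character = c(1, 3, 6, 7, 10, 11)))
  names(f)[1:11] <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                      "rnext", "pnext", "tlen", "seq", "qual")
  f[, mate := ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L)]
  f[, mapped := bitwAnd(flag, 4L) == 0L]
  f[, strand := ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")]
  f[, dup := bitwAnd(flag, 1024L) > 0L]
  f[, proper := bitwAnd(flag, 2L) > 0L]
  f[, clipl := ifelse(grepl("^[0-9]+S", cigar),
                      as.integer(sub("S.*", "", cigar)), 0L)]
  f[, alen := ifelse(mapped,
                     as.integer(sub("M.*", "",
                                    sub("^[0-9]+S", "", cigar))), 0L)]
  f[, clipr := ifelse(grepl("M[0-9]+S$", cigar),
                      as.integer(sub("S$", "",
                                     sub(".*M", "", cigar))), 0L)]
  # undo SAM's reverse-complement storage
  neg <- f$mapped & f$strand == "-"
  f$seq[neg] <- revcomp(f$seq[neg])
  f$qual[neg] <- vapply(strsplit(f$qual[neg], ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  m1 <- f[f$mate == 1L]
  m2 <- f[f$mate == 2L]
  m2 <- m2[match(m1$qname, m2$qname)]
  aln <- data.table::data.table(
    qname = m1$qname,
    chrom1 = ifelse(m1$mapped, m1$rname, NA_character_), pos1 = m1$pos,
    strand1 = m1$strand, mapq1 = m1$mapq, clipl1 = m1$clipl,
    clipr1 = m1$clipr, alen1 = m1$alen, score1 = NA_integer_,
    chrom2 = ifelse(m2$mapped, m2$rname, NA_character_), pos2 = m2$pos,
    strand2 = m2$strand, mapq2 = m2$mapq, clipl2 = m2$clipl,
    clipr2 = m2$clipr, alen2 = m2$alen, score2 = NA_integer_,
    seq1 = m1$seq, qual1 = m1$qual, seq2 = m2$seq, qual2 = m2$qual,
    dup = m1$dup, isize = abs(m1$tlen), proper = m1$proper)
  aln[is.na(chrom1), pos1 := NA_integer_]
  aln[is.na(chrom2), pos2 := NA_integer_]
  aln[isize == 0L, isize := NA_integer_]
  data.table::setattr(aln, "class", c("alignment_set", class(aln)))
  aln
}
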