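# Reference genome construction for the synthetic study.
#
# The reference is a random background into which mobile-element features are
# planted: L1 copies (a shared pseudo-consensus diverging only at per-copy
# diagnostic bases) with polyA tails and a unique transducible 3' flank, Alu
# copies with polyA tails, bare polyA runs mimicking the longest runs of a
# real assembly, and annotation-only gene intervals. Because the background
# is i.i.d. random sequence, every donor's 3' flank is unique genome-wide.

#' Build the synthetic reference genome
#'
#' @param config a [sim_config()] object.
#' @return an object of class `genome_model`: chromosome sequences, element
#'   annotations, donor records (reference and non-reference), planted polyA
#'   runs, gene intervals and the shared element consensus sequences.
#' @export
build_reference <- function(config) {
  validate_config(config)
  set.seed(child_seed(config$seed, "reference"))

  chrom_len <- rep(floor(config$genome_length / config$n_chromosomes),
                   config$n_chromosomes)
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))

  # element bodies end in non-A bases (the polyA signal context), keeping
  # the boundary between element sequence and appended tails identifiable
  end_nonA <- function(s) {
    n <- nchar(s)
    substr(s, n - 2L, n) <- paste(sample(c("C", "G", "T"), 3L, replace = TRUE),
                                  collapse = "")
    s
  }
  consensus_l1 <- end_nonA(random_dna(config$l1_length))
  consensus_alu <- end_nonA(random_dna(config$alu_length))

  # --- feature sizing -------------------------------------------------------
  n_feat <- config$n_reference_L1 + config$n_alu +
    length(config$planted_polya_lengths) + config$n_nonreference_L1
  margin <- 5000L
  gap <- 3000L
  block_max <- config$l1_length + max(config$element_tail_range) +
    config$flank_length
  need <- n_feat * (block_max + gap) + 2 * margin * config$n_chromosomes
  if (need > sum(chrom_len))
    stop(sprintf(paste0("genome too short to host requested features: need ",
                        "about %d bp but genome is %d bp"),
                 need, sum(chrom_len)))

  seqs <- vapply(chrom_len, random_dna, character(1))
  names(seqs) <- chrom_names

  # non-overlapping placement (uniform, rejection-sampled)
  placed <- lapply(chrom_names, function(cn) cbind(start = numeric(0),
                                                   end = numeric(0)))
  names(placed) <- chrom_names
  place_block <- function(width) {
    for (try in 1:2000) {
      cn <- sample(chrom_names, 1L)
      len <- chrom_len[match(cn, chrom_names)]
      s <- sample.int(len - 2L * margin - width, 1L) + margin
      e <- s + width - 1L
      occ <- placed[[cn]]
      if (nrow(occ) == 0 ||
          all(s > occ[, "end"] + gap | e < occ[, "start"] - gap)) {
        placed[[cn]] <<- rbind(occ, cbind(start = s, end = e))
        return(list(chrom = cn, start = s, end = e))
      }
    }
    stop("failed to place a feature after bounded retries; enlarge the genome")
  }
  plant <- function(chrom, start, block) {
    substr(seqs[[chrom]], start, start + nchar(block) - 1L) <<- block
  }

  diag_bases <- function(consensus, n = 3L) {
    off <- sort(sample.int(nchar(consensus) - 3L, n))
    orig <- strsplit(substring(consensus, off, off), "")
    base <- vapply(seq_along(off), function(i) {
      sample(setdiff(c("A", "C", "G", "T"), substring(consensus, off[i], off[i])), 1L)
    }, character(1))
    data.frame(offset = off, base = base, stringsAsFactors = FALSE)
  }
  apply_diag <- function(consensus, db) {
    for (i in seq_len(nrow(db)))
      substr(consensus, db$offset[i], db$offset[i]) <- db$base[i]
    consensus
  }

  donors <- list()
  elements <- list()
  polya_planted <- list()

  # give each polyA addition site a non-A 3-base context (C/G is its own
  # complement set, so this reads non-A on either strand), keeping measured
  # tail lengths from running into flank sequence
  mark_site_context <- function(chrom, sites, strand) {
    for (g in sites) {
      span <- if (strand == "+") (g - 2L):g else g:(g + 2L)
      for (gg in span) {
        if (gg >= 1L && gg <= nchar(seqs[[chrom]]))
          substr(seqs[[chrom]], gg, gg) <<- sample(c("C", "G"), 1L)
      }
    }
  }

  # --- reference L1 donors --------------------------------------------------
  for (i in seq_len(config$n_reference_L1)) {
    db <- diag_bases(consensus_l1)
    elem <- apply_diag(consensus_l1, db)
    tail_len <- sample(seq(config$element_tail_range[1],
                           config$element_tail_range[2]), 1L)
    strand <- sample(c("+", "-"), 1L)
    block_plus <- paste0(elem, strrep("A", tail_len))
    loc <- place_block(nchar(block_plus) + config$flank_length)
    if (strand == "+") {
      plant(loc$chrom, loc$start, block_plus)
      el_start <- loc$start
      el_end <- loc$start + nchar(block_plus) - 1L
      flank_start <- el_end + 1L
      flank_end <- flank_start + config$flank_length - 1L
    } else {
      # minus strand: genomic block is the reverse complement; the
      # transducible flank lies on the genomic left, read rightward -> leftward
      plant(loc$chrom, loc$start + config$flank_length, revcomp(block_plus))
      el_start <- loc$start + config$flank_length
      el_end <- el_start + nchar(block_plus) - 1L
      flank_end <- el_start - 1L
      flank_start <- flank_end - config$flank_length + 1L
    }
    # guard base so the tail run length stays exactly as configured
    guard <- if (strand == "+") el_end + 1L else el_start - 1L
    substr(seqs[[loc$chrom]], guard, guard) <- sample(c("C", "G"), 1L)
    nsite <- sample(2:3, 1L)
    site_off <- sort(sample(500:1400, nsite))
    sites <- if (strand == "+") flank_start - 1L + site_off else
      flank_end + 1L - site_off
    mark_site_context(loc$chrom, sites, strand)
    donors[[length(donors) + 1L]] <- list(
      id = sprintf("L1ref_%d", i), family = "L1", in_reference = TRUE,
      chrom = loc$chrom, start = el_start, end = el_end, strand = strand,
      tail_len = tail_len, insertion_point = NA_integer_,
      flank_chrom = loc$chrom, flank_start = flank_start,
      flank_end = flank_end, polya_sites = sites, polya_site_offsets = site_off,
      diagnostic = db, element_seq = elem, hot = TRUE)
    elements[[length(elements) + 1L]] <- data.frame(
      id = sprintf("L1ref_%d", i), family = "L1", chrom = loc$chrom,
      start = el_start, end = el_end, strand = strand, tail_len = tail_len,
      stringsAsFactors = FALSE)
  }

  # --- reference Alu copies -------------------------------------------------
  for (i in seq_len(config$n_alu)) {
    db <- diag_bases(consensus_alu, 2L)
    elem <- apply_diag(consensus_alu, db)
    tail_len <- sample(seq(config$element_tail_range[1],
                           config$element_tail_range[2]), 1L)
    strand <- sample(c("+", "-"), 1L)
    block <- paste0(elem, strrep("A", tail_len))
    if (strand == "-") block <- revcomp(block)
    loc <- place_block(nchar(block))
    plant(loc$chrom, loc$start, block)
    guard <- if (strand == "+") loc$end + 1L else loc$start - 1L
    substr(seqs[[loc$chrom]], guard, guard) <- sample(c("C", "G"), 1L)
    elements[[length(elements) + 1L]] <- data.frame(
      id = sprintf("Alu_%d", i), family = "Alu", chrom = loc$chrom,
      start = loc$start, end = loc$end, strand = strand, tail_len = tail_len,
      stringsAsFactors = FALSE)
  }

  # --- bare polyA runs (longest runs in the reference) ----------------------
  # guard bases keep adjacent random background from extending a run
  for (i in seq_along(config$planted_polya_lengths)) {
    w <- config$planted_polya_lengths[i]
    loc <- place_block(w + 2L)
    plant(loc$chrom, loc$start, paste0("C", strrep("A", w), "G"))
    polya_planted[[length(polya_planted) + 1L]] <- data.frame(
      id = sprintf("polyA_run_%d", i), chrom = loc$chrom,
      start = loc$start + 1L, end = loc$start + w, length = w,
      stringsAsFactors = FALSE)
  }

  # --- non-reference (polymorphic) donors -----------------------------------
  # These sit at an insertion point in carrier individuals only; their
  # transducible flank is the reference sequence just downstream of that
  # point. Modelled on the plus strand.
  for (i in seq_len(config$n_nonreference_L1)) {
    db <- diag_bases(consensus_l1)
    elem <- apply_diag(consensus_l1, db)
    tail_len <- sample(seq(config$element_tail_range[1],
                           config$element_tail_range[2]), 1L)
    loc <- place_block(config$flank_length)  # reserve the flank region only
    ip <- loc$start - 1L                     # element inserted after this base
    flank_start <- loc$start
    flank_end <- loc$start + config$flank_length - 1L
    nsite <- sample(2:3, 1L)
    site_off <- sort(sample(500:1400, nsite))
    mark_site_context(loc$chrom, flank_start - 1L + site_off, "+")
    donors[[length(donors) + 1L]] <- list(
      id = sprintf("L1poly_%d", i), family = "L1", in_reference = FALSE,
      chrom = loc$chrom, start = NA_integer_, end = NA_integer_, strand = "+",
      tail_len = tail_len, insertion_point = ip,
      flank_chrom = loc$chrom, flank_start = flank_start,
      flank_end = flank_end, polya_sites = flank_start - 1L + site_off,
      polya_site_offsets = site_off,
      diagnostic = db, element_seq = elem, hot = FALSE)
  }

  # --- annotation-only gene intervals ---------------------------------------
  genes <- NULL
  if (config$n_genes > 0) {
    rows <- vector("list", config$n_genes)
    gene_max <- max(6000L, min(50000L, as.integer(min(chrom_len) %/%
                                                    (2L * config$n_genes))))
    for (i in seq_len(config$n_genes)) {
      w <- sample(5000:gene_max, 1L)
      loc <- place_block(w)
      rows[[i]] <- data.frame(gene = sprintf("GENE%03d", i), chrom = loc$chrom,
                              start = loc$start, end = loc$end,
                              strand = sample(c("+", "-"), 1L),
                              stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, rows)
  }

  gm <- list(seqs = seqs, chrom_lengths = stats::setNames(chrom_len, chrom_names),
             elements = do.call(rbind, elements),
             polya_planted = do.call(rbind, polya_planted),
             donors = donors, genes = genes,
             consensus_l1 = consensus_l1, consensus_alu = consensus_alu,
             config = config)
  class(gm) <- "genome_model"
  gm
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$seqs), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp\n")
  cat("  elements:", nrow(x$elements), " planted polyA runs:",
      if (is.null(x$polya_planted)) 0L else nrow(x$polya_planted), "\n")
  nref <- sum(vapply(x$donors, function(d) d$in_reference, logical(1)))
  cat("  donors:", nref, "reference L1,", length(x$donors) - nref,
      "non-reference L1\n")
  invisible(x)
}

# feature intervals that somatic inserts must not overlap
feature_intervals <- function(genome) {
  f1 <- genome$elements[, c("chrom", "start", "end")]
  f2 <- if (!is.null(genome$polya_planted))
    genome$polya_planted[, c("chrom", "start", "end")] else NULL
  f3 <- do.call(rbind, lapply(genome$donors, function(d)
    data.frame(chrom = d$flank_chrom, start = d$flank_start,
               end = d$flank_end, stringsAsFactors = FALSE)))
  f4 <- do.call(rbind, lapply(genome$donors, function(d) {
    if (d$in_reference) return(NULL)
    data.frame(chrom = d$chrom, start = d$insertion_point,
               end = d$insertion_point + 1L, stringsAsFactors = FALSE)
  }))
  do.call(rbind, Filter(Negate(is.null), list(f1, f2, f3, f4)))
}

#' Write the reference genome and its annotations
#'
#' FASTA via Biostrings; annotations as BED (0-based half-open): planted
#' elements, the hot-L1 list, the non-reference donor catalogue (insertion
#' points) and gene intervals.
#'
#' @param genome a `genome_model`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reference <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seqs), fa)
  el <- file.path(dir, "elements.bed")
  if (is.null(genome$elements) || nrow(genome$elements) == 0) {
    write_bed(as_bed(character(0), integer(0), integer(0)), el)
  } else {
    write_bed(with(genome$elements,
                   as_bed(chrom, start, end, id, 0L, strand)), el)
  }
  hot <- Filter(function(d) isTRUE(d$hot), genome$donors)
  hotbed <- file.path(dir, "hot_l1.bed")
  write_bed(do.call(rbind, c(lapply(hot, function(d)
    as_bed(d$chrom, d$start, d$end, d$id, 0L, d$strand)),
    list(as_bed(character(0), integer(0), integer(0))))), hotbed)
  nonref <- Filter(function(d) !d$in_reference, genome$donors)
  polybed <- file.path(dir, "nonreference_donors.bed")
  write_bed(do.call(rbind, c(lapply(nonref, function(d)
    as_bed(d$chrom, d$insertion_point, d$insertion_point, d$id, 0L, d$strand)),
    list(as_bed(character(0), integer(0), integer(0))))), polybed)
  paths <- c(fa, el, hotbed, polybed)
  if (!is.null(genome$genes)) {
    gbed <- file.path(dir, "genes.bed")
    write_bed(with(genome$genes, as_bed(chrom, start, end, gene, 0L, strand)),
              gbed)
    paths <- c(paths, gbed)
  }
  invisible(paths)
}

#' Donor sequence library
#'
#' Per donor, the element sequence (5'->3' in transcription orientation,
#' excluding the polyA tail), its transducible flank sequence, and their
#' concatenation as mobilised transcripts read them.
#'
#' @param genome a `genome_model`.
#' @return named list of lists with `element`, `flank`, `cat`, `diagnostic`.
#' @export
donor_library <- function(genome) {
  out <- lapply(genome$donors, function(d) {
    flank <- substr(genome$seqs[[d$flank_chrom]], d$flank_start, d$flank_end)
    if (d$strand == "-") flank <- revcomp(flank)
    list(id = d$id, element = d$element_seq, flank = flank,
         cat = paste0(d$element_seq, flank), diagnostic = d$diagnostic,
         tail_len = d$tail_len, in_reference = d$in_reference,
         polya_site_offsets = d$polya_site_offsets,
         flank_chrom = d$flank_chrom, flank_start = d$flank_start,
         flank_end = d$flank_end, strand = d$strand)
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}
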