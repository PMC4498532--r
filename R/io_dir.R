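# Plain-text persistence of a simulated study directory, so that the
# command-line stages (simulate | align | call-junctions | ...) can hand
# results to each other through standard files only.

#' Simulate a study to a directory of standard files
#'
#' Builds the reference and every sample of the configured study and writes:
#' the reference FASTA with element/hot-L1/non-reference-donor/gene BEDs,
#' the donor library (TSV + element FASTA, including the shared consensus
#' sequences), per-sample paired FASTQ (tumours `T..`, matched normals
#' `T..N`, panel `P..`), per-tumour truth TSV/BED and the config as YAML.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created).
#' @return invisibly, `outdir`.
#' @export
simulate_to_dir <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- build_reference(config)
  write_reference(genome, outdir)
  write_sim_config(config, file.path(outdir, "config.yaml"))

  ddir <- file.path(outdir, "donors")
  dir.create(ddir, showWarnings = FALSE)
  dtab <- do.call(rbind, lapply(genome$donors, function(d) data.frame(
    id = d$id, family = d$family, in_reference = d$in_reference,
    chrom = d$chrom, start = d$start, end = d$end, strand = d$strand,
    tail_len = d$tail_len, insertion_point = d$insertion_point,
    flank_chrom = d$flank_chrom, flank_start = d$flank_start,
    flank_end = d$flank_end,
    polya_site_offsets = paste(d$polya_site_offsets, collapse = ","),
    diagnostic = paste(sprintf("%d%s", d$diagnostic$offset,
                               d$diagnostic$base), collapse = ","),
    stringsAsFactors = FALSE)))
  utils::write.table(dtab, file.path(ddir, "donors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  el <- Biostrings::DNAStringSet(c(
    stats::setNames(vapply(genome$donors, `[[`, character(1), "element_seq"),
                    vapply(genome$donors, `[[`, character(1), "id")),
    consensus_L1 = genome$consensus_l1,
    consensus_Alu = genome$consensus_alu))
  Biostrings::writeXStringSet(el, file.path(ddir, "donor_elements.fa"))

  sdir <- file.path(outdir, "samples")
  tdir <- file.path(outdir, "truth")
  dir.create(sdir, showWarnings = FALSE)
  dir.create(tdir, showWarnings = FALSE)
  for (i in seq_len(config$n_panel_normals)) {
    pid <- sprintf("P%02d", i)
    indiv <- simulate_individual(genome, config, pid)
    write_fastq(generate_read_pairs(indiv$seqs, config, pid),
                file.path(sdir, pid))
  }
  for (i in seq_len(config$n_tumours)) {
    tid <- sprintf("T%02d", i)
    sim <- simulate_tumour(genome, config, tid)
    write_fastq(generate_read_pairs(sim$tumour, config, tid),
                file.path(sdir, tid))
    write_fastq(generate_read_pairs(sim$normal, config, paste0(tid, "N")),
                file.path(sdir, paste0(tid, "N")))
    write_truth(sim$truth, file.path(tdir, paste0(tid, ".tsv")),
                file.path(tdir, paste0(tid, ".bed")))
  }
  invisible(outdir)
}

#' Reload the genome model of a simulated study directory
#'
#' Reconstructs a `genome_model` from the plain-text files written by
#' [simulate_to_dir()].
#'
#' @param outdir directory written by [simulate_to_dir()].
#' @return a `genome_model`.
#' @export
load_genome_dir <- function(outdir) {
  fa <- Biostrings::readDNAStringSet(file.path(outdir, "reference.fa"))
  seqs <- stats::setNames(as.character(fa), names(fa))
  config <- read_sim_config(file.path(outdir, "config.yaml"))
  dtab <- utils::read.table(file.path(outdir, "donors", "donors.tsv"),
                            sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, na.strings = "NA")
  el <- Biostrings::readDNAStringSet(file.path(outdir, "donors",
                                               "donor_elements.fa"))
  donors <- lapply(seq_len(nrow(dtab)), function(i) {
    dd <- dtab[i, ]
    diag_parts <- strsplit(dd$diagnostic, ",", fixed = TRUE)[[1]]
    diagnostic <- data.frame(
      offset = as.integer(sub("[ACGT]$", "", diag_parts)),
      base = sub("^[0-9]+", "", diag_parts), stringsAsFactors = FALSE)
    site_off <- as.integer(strsplit(dd$polya_site_offsets, ",")[[1]])
    sites <- if (is.na(dd$start)) dd$flank_start - 1L + site_off
      else if (dd$strand == "+") dd$flank_start - 1L + site_off
      else dd$flank_end + 1L - site_off
    list(id = dd$id, family = dd$family, in_reference = dd$in_reference,
         chrom = dd$chrom, start = dd$start, end = dd$end,
         strand = dd$strand, tail_len = dd$tail_len,
         insertion_point = dd$insertion_point, flank_chrom = dd$flank_chrom,
         flank_start = dd$flank_start, flank_end = dd$flank_end,
         polya_sites = sites, polya_site_offsets = site_off,
         diagnostic = diagnostic,
         element_seq = as.character(el[[dd$id]]),
         hot = dd$in_reference)
  })
  elements <- NULL
  ebed <- file.path(outdir, "elements.bed")
  if (file.size(ebed) > 0) {
    eb <- read_bed(ebed)
    elements <- data.frame(id = eb$name,
                           family = ifelse(grepl("^Alu", eb$name), "Alu", "L1"),
                           chrom = eb$chrom, start = eb$start + 1L,
                           end = eb$end, strand = eb$strand,
                           tail_len = NA_integer_, stringsAsFactors = FALSE)
  }
  genes <- NULL
  gbed <- file.path(outdir, "genes.bed")
  if (file.exists(gbed) && file.size(gbed) > 0) {
    gb <- read_bed(gbed)
    genes <- data.frame(gene = gb$name, chrom = gb$chrom,
                        start = gb$start + 1L, end = gb$end,
                        strand = gb$strand, stringsAsFactors = FALSE)
  }
  gm <- list(seqs = seqs,
             chrom_lengths = stats::setNames(nchar(seqs), names(seqs)),
             elements = elements, polya_planted = NULL, donors = donors,
             genes = genes, consensus_l1 = as.character(el[["consensus_L1"]]),
             consensus_alu = as.character(el[["consensus_Alu"]]),
             config = config)
  class(gm) <- "genome_model"
  gm
}
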