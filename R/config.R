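#' Simulation configuration
#'
#' Collects every tunable of the synthetic tumour/normal study in one
#' validated object. The defaults describe the emulated sequencing study:
#' 100 bp paired-end reads from ~320 bp fragments at 50-fold depth, tumours
#' carrying on average 40 somatic L1-mediated insertions with 5' truncation,
#' a 50% chance of 3' transduction, 25-60 bp polyA tails, target-site
#' duplications up to 20 bp (occasionally a small deletion instead) and a 20%
#' rate of 5' inversion. The reference carries planted L1/Alu elements with
#' polyA tails plus three bare polyA runs of 90, 83 and 79 bp, mirroring the
#' longest polyA runs of a real reference assembly.
#'
#' @param seed integer seed; a fixed seed makes every simulator output
#'   byte-identical across runs.
#' @param genome_length total reference length in bp (split over chromosomes).
#' @param n_chromosomes number of chromosomes.
#' @param n_reference_L1 number of reference L1 copies (all treated as "hot",
#'   i.e. potentially active, and given a transducible 3' flank).
#' @param n_nonreference_L1 number of polymorphic donor L1s absent from the
#'   reference, located only by their insertion point.
#' @param n_alu number of reference Alu copies (polyA-tailed decoys).
#' @param planted_polya_lengths lengths of bare plus-strand polyA runs planted
#'   in the reference.
#' @param inserts_per_tumour list(mu=, size=): negative-binomial law for the
#'   somatic insert count per tumour.
#' @param p_transduction probability an insert carries transduced 3' flank.
#' @param truncation_mean geometric mean of retained donor 3' length (bp);
#'   heavy mass below 300 bp reflects frequent severe 5' truncation.
#' @param polya_tail_range min/max polyA tail length (bp); min must be >= 20.
#' @param tsd_values,tsd_weights support and weights of the target-site
#'   duplication length law over -5..20 (negative = small target deletion).
#' @param p_inversion probability of a 5' (twin-priming) inversion.
#' @param inversion_len_range min/max inverted 5' prefix length (bp).
#' @param inversion_gap_range min/max gap between the inverted prefix's donor
#'   source and the start of the forward-matching remainder (bp).
#' @param read_length read length (bp).
#' @param fragment_mean,fragment_sd fragment-length normal law (bp).
#' @param coverage fold sequence coverage per sample.
#' @param base_error_rate substitution error probability per sequenced base.
#' @param lowq_read_rate fraction of reads whose whole quality string is the
#'   minimum symbol (emulating unusable reads caught by the quality filter).
#' @param n_tumours number of tumour/matched-normal individuals.
#' @param n_panel_normals number of additional unrelated panel individuals.
#' @param p_donor_carrier probability that an individual carries a given
#'   non-reference donor in its germline.
#' @param l1_length,alu_length synthetic element consensus lengths (bp).
#' @param flank_length transducible 3' flank length recorded per donor (bp).
#' @param element_tail_range min/max polyA tail length on planted elements.
#' @param n_genes annotation-only gene intervals emitted with the reference.
#' @return an object of class `retroscan_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       n_chromosomes = 2L,
                       n_reference_L1 = 6L,
                       n_nonreference_L1 = 2L,
                       n_alu = 6L,
                       planted_polya_lengths = c(90L, 83L, 79L),
                       inserts_per_tumour = list(mu = 40, size = 10),
                       p_transduction = 0.5,
                       truncation_mean = 150,
                       polya_tail_range = c(25L, 60L),
                       tsd_values = -5:20,
                       tsd_weights = NULL,
                       p_inversion = 0.20,
                       inversion_len_range = c(10L, 40L),
                       inversion_gap_range = c(0L, 60L),
                       read_length = 100L,
                       fragment_mean = 320,
                       fragment_sd = 40,
                       coverage = 50,
                       base_error_rate = 0.001,
                       lowq_read_rate = 0.001,
                       n_tumours = 5L,
                       n_panel_normals = 5L,
                       p_donor_carrier = 0.75,
                       l1_length = 3000L,
                       alu_length = 300L,
                       flank_length = 1500L,
                       element_tail_range = c(20L, 40L),
                       n_genes = 20L) {
  if (is.null(tsd_weights)) {
    # default mass concentrated on duplications of 4-18 bp
    tsd_weights <- ifelse(tsd_values < 0, 0.01,
                   ifelse(tsd_values == 0, 0.03,
                   ifelse(tsd_values %in% 1:3, 0.02,
                   ifelse(tsd_values %in% 4:18, 0.80 / 15, 0.015))))
  }
  cfg <- list(seed = as.integer(seed), genome_length = as.numeric(genome_length),
              n_chromosomes = as.integer(n_chromosomes),
              n_reference_L1 = as.integer(n_reference_L1),
              n_nonreference_L1 = as.integer(n_nonreference_L1),
              n_alu = as.integer(n_alu),
              planted_polya_lengths = as.integer(planted_polya_lengths),
              inserts_per_tumour = inserts_per_tumour,
              p_transduction = p_transduction,
              truncation_mean = truncation_mean,
              polya_tail_range = as.integer(polya_tail_range),
              tsd_values = as.integer(tsd_values),
              tsd_weights = tsd_weights / sum(tsd_weights),
              p_inversion = p_inversion,
              inversion_len_range = as.integer(inversion_len_range),
              inversion_gap_range = as.integer(inversion_gap_range),
              read_length = as.integer(read_length),
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              coverage = coverage, base_error_rate = base_error_rate,
              lowq_read_rate = lowq_read_rate,
              n_tumours = as.integer(n_tumours),
              n_panel_normals = as.integer(n_panel_normals),
              p_donor_carrier = p_donor_carrier,
              l1_length = as.integer(l1_length),
              alu_length = as.integer(alu_length),
              flank_length = as.integer(flank_length),
              element_tail_range = as.integer(element_tail_range),
              n_genes = as.integer(n_genes))
  class(cfg) <- "retroscan_config"
  validate_config(cfg)
  cfg
}

#' @export
print.retroscan_config <- function(x, ...) {
  cat("retroscan simulation config\n")
  cat(sprintf("  seed %d | genome %.2g bp on %d chromosome(s)\n",
              x$seed, x$genome_length, x$n_chromosomes))
  cat(sprintf("  donors: %d reference L1, %d non-reference L1, %d Alu\n",
              x$n_reference_L1, x$n_nonreference_L1, x$n_alu))
  cat(sprintf("  tumours: %d (+%d panel normals), ~%g inserts/tumour\n",
              x$n_tumours, x$n_panel_normals, x$inserts_per_tumour$mu))
  cat(sprintf("  reads: %d bp pairs, fragments %g +/- %g, %gx, error %g\n",
              x$read_length, x$fragment_mean, x$fragment_sd, x$coverage,
              x$base_error_rate))
  invisible(x)
}

validate_config <- function(cfg) {
  probs <- c(cfg$p_transduction, cfg$p_inversion, cfg$base_error_rate,
             cfg$lowq_read_rate, cfg$p_donor_carrier)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (cfg$polya_tail_range[1] < 20L)
    stop("polya_tail_range minimum must be >= 20 (the polyA-scan detection floor)")
  if (cfg$read_length > cfg$fragment_mean)
    stop("read_length must not exceed fragment_mean")
  if (cfg$coverage <= 0) stop("coverage must be positive")
  if (length(cfg$tsd_values) != length(cfg$tsd_weights))
    stop("tsd_values and tsd_weights lengths differ")
  invisible(cfg)
}

#' Write / read a simulation config as YAML
#'
#' @param cfg a `retroscan_config`.
#' @param path file path.
#' @return `read_sim_config` returns a validated `retroscan_config`.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw[names(raw) %in% names(formals(sim_config))])
}
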