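# Internal helpers shared across the pipeline.

#' Reverse-complement character sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] keeping
#' plain character vectors as the working representation.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Width of a 1-based inclusive interval
#'
#' Human-readable reports use 1-based inclusive coordinates throughout, so the
#' printed interval chr:start-end spans `end - start + 1` bases.
#'
#' @param start,end integer vectors, 1-based inclusive.
#' @return integer vector of widths.
#' @export
interval_span <- function(start, end) {
  stopifnot(all(end >= start))
  as.integer(end - start + 1L)
}

#' Integer percentage, rounding half away from zero
#'
#' `round()` in R rounds half to even; report tables round half up
#' (e.g. 42/45 -> 93).
#'
#' @param numerator,denominator non-negative counts; `denominator > 0`.
#' @return integer percent in 0..100, or `NA` when the denominator is zero.
#' @export
summarize_percent <- function(numerator, denominator) {
  if (length(denominator) == 1L && denominator == 0) return(NA_integer_)
  stopifnot(all(denominator > 0))
  as.integer(floor(100 * numerator / denominator + 0.5))
}

# Chain sorted positions: new group whenever the gap to the previous position
# exceeds `window`. Returns integer group ids in the original order.
chain_positions <- function(pos, window) {
  if (length(pos) == 0L) return(integer(0))
  o <- order(pos)
  p <- pos[o]
  grp <- cumsum(c(1L, as.integer(diff(p) > window)))
  out <- integer(length(pos))
  out[o] <- grp
  out
}

# 1-based inclusive -> BED (0-based half-open) data.frame
as_bed <- function(chrom, start, end, name = ".", score = 0L, strand = "*") {
  n <- length(chrom)
  data.frame(chrom = chrom, start = as.integer(start - 1L),
             end = as.integer(end), name = rep_len(name, n),
             score = rep_len(score, n), strand = rep_len(strand, n),
             stringsAsFactors = FALSE)
}

write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  names(bed) <- cols[seq_len(ncol(bed))]
  bed
}

# distance between two 1-based inclusive intervals (0 when overlapping)
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

# derive a child RNG seed deterministically from a base seed; kept < 2^31
child_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) else x
  })))
  as.integer((sum(parts * (seq_along(parts) * 7919)) %% 2147483587) + 1)
}
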