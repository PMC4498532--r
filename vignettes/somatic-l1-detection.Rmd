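---
title: "Detecting somatic L1-mediated insertions from tumour/normal paired-end sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic L1-mediated insertions from tumour/normal paired-end sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroscan)
```

## The problem

Active LINE-1 (L1) retrotransposons copy themselves — and, through
transcriptional read-through past their own polyA signal, unique genomic
sequence downstream of themselves ("3' transduction") — into new genomic
locations. In tumours this happens somatically and at scale. In paired-end
whole-genome sequencing these insertions are a systematic confounder: a new
insert looks like a translocation junction when part of it maps uniquely
(transduced sequence), like a rearrangement involving a reference element or
a long reference polyA run when an aligner confidently but wrongly places
polyA-rich reads, or like an entirely artefactual junction when the two
reads of one pair, both inside one insert, are mapped to two different loci
("split mappings"). Conversely, most inserts are so 5'-truncated that they
carry little or no mappable sequence at all — often just a polyA tail — and
are invisible to conventional structural-variant calling.

`retroscan` re-implements, as a tested and reusable pipeline, the
computational strategy for finding and characterising these events:

1. **Junction calling** from discordant read pairs, with subclustering,
   matched-normal and panel-of-normals subtraction, a small-inversion
   library-artefact filter and a "plausible normal alignment" filter.
2. **Source-element discovery**: recurrent breakpoint clusters across
   tumours, classified as reference-L1 transduction, non-reference
   (polymorphic) L1 transduction, reference-element/polyA mapping, or
   unclassified, plus split-mapping detection.
3. **A tumour-specific polyA scan**: reads containing a long A/T run whose
   mates map confidently, grouped into candidate insertion sites, with
   quality, support, normal-subtraction and reference-polyA filters, a
   tumour/normal swap control and automated soft-clip curation.
4. **Insert anatomy** of resolved inserts: target-site duplication (TSD),
   polyA tail, 5' (twin-priming) inversion, donor assignment via diagnostic
   bases, transduced extent and polyA addition site.

Because real tumour cohorts of this kind are access-controlled, the package
ships a **simulator** of the retrotransposition mechanism and of the
sequencing process; every detection claim the package makes is demonstrated
against that simulator's ground truth.

## The simulated study

`sim_config()` fixes the study conditions. The defaults describe the
emulated experiment: 100 bp paired-end reads from fragments of mean 320 bp
(sd 40) at 50-fold depth — within the published library ranges (median
fragment sizes roughly 280-370 bp, median absolute deviations of a few tens
of bp, depth at least 50x); five tumour/matched-normal individuals plus
five unrelated panel normals on a 2 Mb two-chromosome reference; about 40
somatic inserts per tumour (negative-binomial, size 10 — overdispersion is
characteristic of per-tumour insert counts, which in practice range from
zero to hundreds).

The reference carries:

* reference L1 copies (default 6), each a copy of a seed-generated
  pseudo-L1 consensus diverging only at 3 per-copy *diagnostic bases*, with
  a 20-40 bp polyA tail and a unique downstream transducible flank carrying
  2-3 polyA addition sites 500-1400 bp from the element (observed
  transduced tracts are mostly bounded 0.8-1.3 kb from the element, with
  occasional longer ones);
* non-reference (polymorphic) donor L1s (default 2) that exist only in
  carrier individuals (carrier probability 0.75, bracketing the 25-77%
  population frequencies reported for the two best-known such donors),
  located on the reference only by their insertion point;
* Alu copies with polyA tails, and three bare polyA runs of 90, 83 and
  79 bp, mimicking the longest polyA runs of a real reference assembly —
  the loci that capture mismapped polyA reads;
* annotation-only gene intervals for the gene-effect reports.

Somatic inserts follow the mechanism: optional 3' transduction up to a
sampled polyA addition site (probability 0.5), geometric 5' truncation of
the retained donor 3' end (mean 150 bp, so most inserts carry little or no
L1 sequence, matching the observation that severe truncation is the norm),
a 25-60 bp polyA tail, a target-site duplication drawn from -5..20 bp with
most mass at 4-18 bp (negative values model small target deletions), 20%
5' inversions (twin priming) with a 10-40 bp inverted prefix separated from
the forward-matching remainder by a 0-60 bp donor gap, and uniform insert
orientation.

### What the simulator deliberately does not model

Indel sequencing errors (substitutions only, biased to low-quality
positions); chimeric library artefacts other than the small-inversion
class; somatic SNVs/CNVs and normal-cell contamination of the tumour;
re-mobilisation chains in which a somatic insert transduces its own new
flank (a documented phenomenon, left as an extension); GC or mappability
coverage bias; and polymerase slippage in polyA tails (tail lengths are
exact in simulated data, so the anatomy round-trip can assert them
tightly). Passing the acceptance suite therefore demonstrates correctness
of the algorithms under clean conditions at realistic scale, not robustness
to every artefact of real libraries.

Three simulator choices trade realism for identifiable ground truth, all
confined to a few bases: planted polyA runs and element tails get non-A
guard bases so their lengths are exact; each polyA addition site gets a
3-base non-A context (C/G, self-complementary as a set) so measured tail
lengths do not run into flank sequence; and nick sites avoid homopolymer
steps (`ref[p-1] != ref[p]`) so the planted TSD length is the unique
longest duplication at the junction. Real TSD calls carry exactly this
ambiguity; the simulator removes it so that "recovered exactly" is a
meaningful assertion.

## The aligner and its two dialects

The pipeline consumes alignments, so the package includes a deterministic
seed-and-extend aligner (exact 20-mer index, ungapped extension by the
best-scoring segment under +1/-3 scoring, soft-clipped tails; ungapped
because the downstream callers consume discordance and clipping, not
indels, and because it keeps the exhaustive-scan oracle exact). Two
dialects reproduce the qualitative behaviours that matter for polyA-rich
reads:

* **strict** (the default for all calling): a placement needs at least 30
  matching bases outside long (>= 20 bp) homopolymer runs. Mostly-polyA
  reads stay unmapped — the behaviour that motivates the polyA scan.
* **trimming**: placements may be anchored by a read homopolymer run
  (>= 20 bp) matched onto a reference polyA run with as few as 4 matching
  flanking bases, everything else soft-clipped. This reproduces the
  aligner dialect that confidently maps reads to the longest reference
  polyA runs — the "reference element mapping" junction class.

MAPQ is `min(60, 6 * (best - second best))`, 0 on ties. The formula is a
package invention (the original analysis consumed aligner-reported MAPQ);
it is chosen so that unique placements clear the polyA scan's MAPQ >= 30
mate gate and ambiguous placements (e.g. inside element copies, away from
diagnostic bases) do not. Ties break deterministically toward the smallest
(chromosome, position, strand).

Thresholds that matter, with defaults and origin:

| parameter | default | origin |
|---|---|---|
| junction support | >= 3 pairs | stated rule of the original analysis (2 allowed for cleaner libraries) |
| normal/panel subtraction | any matching pair/read | strictest reading of "absent from normals" |
| small inversions discarded | span < 10 kb | stated rule, library artefact |
| plausible normal alignment | >= 90% identity over >= 100 bp | stated rule; ungapped all-offset scan over +-500 bp windows |
| cluster chaining | 1 kb; >= 5 junctions; >= 2 tumours | stated recurrence rule |
| hot-L1 downstream window | 5 kb | covers all reported transduced extents (max ~4.1 kb) with margin |
| polyA read flag | >= 20 consecutive A or T | stated rule; T = minus-strand polyA |
| unusable read | >= 80 consecutive minimum-quality bases | stated rule |
| polyA mate anchor | MAPQ >= 30 | stated rule |
| reference-polyA exclusion | within 500 bp | stated rule (gap of exactly 500 still flagged) |
| polymorphism match | within 1 kb, strand-blind | stated rule |
| curation | +-300 bp window, modal clip point, 90% identity, majority consensus | the original curation was manual; these make it automatic and testable |

## Design choices where the design was genuinely open

* **Coordinates.** Internally everything is 1-based inclusive — the native
  R and SAM convention, shared by IRanges/Biostrings. BED output converts
  to 0-based half-open; reports stay 1-based.
* **Reciprocal junction pairing.** The two junctions of one insertion
  share the target locus within ~TSD + breakpoint noise (window 50 bp),
  but their far sides straddle the *transduced tract*, so the far-side
  window defaults to 2 kb. A single small window on both sides would pair
  almost no transduction insertions.
* **Subclustering.** Members of one subcluster must agree in orientation
  on both sides and chain within `fragment_mean + 4*sd` on both sides
  (connected components under exactly that predicate, verified against an
  O(n^2) oracle). Whether mixed orientations were tolerated originally is
  unstated; requiring consistency is the conservative choice.
* **Classification precedence** is transduction (reference L1, then
  non-reference donor) before reference-element mapping: element-mapped
  read clusters do not in general come from the element they map to, so a
  transduction explanation wins when available. A cluster may include
  breakpoints inside the element's 3' end (truncated inserts carry both
  element and transduced sequence) as long as it reaches unique flank.
* **Polya tail purity.** Tails are measured from the insert's 3' end; a
  non-A base is absorbed only when at least nine consecutive As continue
  the tail past it (at most 1-in-10 impurity). This absorbs slippage-like
  noise without running into A-rich upstream insert sequence (the printed
  13 bp + 49 A worked example measures 49, not more).
* **Donor assignment** is local alignment (Biostrings) of the insert body
  against each donor's element+flank; ties between family copies break by
  diagnostic bases covered, then lexicographically. Assignments need 80%
  identity over at least half the body — the coverage condition guards
  against short coincidental local matches. Element-only inserts that
  cover no diagnostic base are intrinsically ambiguous between identical
  copies; the anatomy reports the deterministic tie-break and the tests
  assert donor identity only where transduced (unique) sequence is
  present.
* **Swap control and background.** The tumour/normal swap rerun uses the
  identical scan with roles exchanged; panel subtraction still applies.
  The proximity-filter discard fraction is assessed among tumour-specific
  candidates (those surviving support and normal subtraction), since
  reference-tail pileups are already removed by the normals.
* **Degenerate inputs.** Reads shorter than the seed are unmapped, not
  errors; breakpoint windows clip at chromosome bounds; zero-insert truth
  tables round-trip as header-only TSVs; candidates with no clipped reads
  curate as "uninformative".

## Problem sizes

The acceptance suite runs one fixed-seed study at the standard scale —
2 Mb reference, 5 tumours + 5 matched normals + 5 panel normals plus a
zero-insert control tumour at 50x (about 0.5 million read pairs per
sample) — in roughly ten minutes on one CPU, inside 2 GB of memory;
per-sample alignments are reduced to the small tables the callers need
(discordant pairs, polyA anchors, soft-clip records) before the next
sample is simulated. Unit and property tests use 0.1-0.6 Mb genomes.
Oracle-equivalence suites use 1000 planted TSD cases, 200 discordant
pairs, 10000 reads and 150 candidate sites.

## Known limitations

* The aligner is ungapped; reads spanning indels would be soft-clipped
  rather than gapped, which real aligners would tolerate. The simulator
  generates no indel errors, so this is self-consistent.
* Transduced extents are read-derived (farthest breakpoint 3' of the donor
  end); extents derived from fully sequenced inserts could differ.
* The polyA scan accepts internal (not only terminal) A/T runs, the more
  sensitive reading of the rule.
* Insert counts by discordant reads collapse reciprocal junction pairs,
  but a reciprocal translocation with a small duplication is
  indistinguishable from an insertion at this level of evidence.
* Inserts with polyA at both ends (a documented oddity) are not modelled;
  the anatomy would report the 3' tail only.
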