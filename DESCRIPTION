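Package: retroscan
Title: Detection and Anatomy of Somatic L1-Mediated Insertions from
    Tumour/Normal Paired-End Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises somatic LINE-1 (L1) mediated mobile
    element insertions, including 3' transductions, from tumour/normal
    paired-end sequencing. Implements discordant read-pair junction calling
    with matched-normal and panel-of-normals subtraction, recurrent
    breakpoint-cluster discovery and source-element classification, a
    tumour-specific polyA-read scan with automated split-read curation, and
    structural anatomy of resolved inserts (target-site duplication, polyA
    tail, 5' inversion, donor assignment, transduced extent). Ships a
    deterministic simulator of the L1 retrotransposition mechanism
    (truncation, transduction, twin-priming inversion, target-site
    duplication) that generates reference genomes, tumour/normal pairs and
    paired-end reads with ground truth, plus a simplified seed-and-extend
    aligner with two dialects reproducing characteristic aligner behaviours
    on polyA-rich reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
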