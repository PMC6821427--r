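Package: prgtyper
Title: HLA Typing by Projection of Linear Alignments onto Population Reference Graphs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds column-structured population reference graphs (PRGs) from
    multiple sequence alignments of reference haplotypes and allele sequences,
    projects linear (SAM-style) read alignments onto the graph, and optimizes
    them in three stages (inspection, polishing, extension) with distinct
    short-read and long-read modes. Diploid genotypes at multi-allelic loci are
    called by maximizing a per-read allele-pair mixture likelihood. Assembled
    contigs are typed by chaining exact-match diagonals into semi-global
    alignments, projecting haplotype annotations onto the contig, and matching
    extracted gene sequences against an allele database by minimum edit
    distance. A self-contained simulator generates haplotype panels, allele
    databases, diploid truth sets, error-bearing short/long reads with SAM
    records, and contigs, so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    Rsamtools,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Alignment, Genetics, SequenceMatching, Software
RoxygenNote: 7.3.3
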