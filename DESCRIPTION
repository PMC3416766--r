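Package: sdrna
Title: Antisense Probe Panels and QC Analytics for RNase H Depletion of
    Abundant RNAs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs tiled, non-overlapping antisense DNA probe panels for
    RNase H-mediated depletion of abundant RNA species (nuclear and
    mitochondrial ribosomal RNAs), screens probes against a transcriptome
    for off-target homology using BLASTN-style affine-gap local alignment,
    and provides the read-processing and depletion quality-control
    analytics that accompany such experiments: 3'-adapter trimming with
    length-dependent mismatch tolerance, classification of uniquely mapped
    reads into rRNA/mitochondrial/exon/intron/intergenic classes,
    depletion-efficiency estimation from before/after read-class
    proportions, and cross-library transcript-abundance correlation.
    A synthetic-data simulator generates references, annotations and
    FFPE-like fragmented read sets with known truth labels so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
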