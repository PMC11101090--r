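Package: SyntenyViews
Title: Processing and Visualization of Pairwise Whole-Genome Alignments
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-processes raw pairwise whole-genome assembly alignments
    (PAF, UCSC chain, or tabular BLAST) into ranked reciprocal-best and
    non-best alignment sets by merging adjacent alignments, splitting on
    large gaps and at overlaps, dropping contained duplicates, and ranking
    by assembly level, identity and length. Provides GFF3/TSV/XLSX export,
    static SVG ideogram and dotplot rendering of synteny with orientation
    and size filters, MinHash (Mash) genome distance with aligner and
    parameter recommendation, genome and CDS alignment-coverage statistics,
    and a synthetic genome-pair simulator with planted rearrangements and
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
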