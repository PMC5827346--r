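Package: edclocus
Title: Annotation and Comparative Analysis of Epidermal Differentiation
    Complex Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and characterization of the Epidermal Differentiation
    Complex (EDC), the amniote gene cluster encoding proteins of skin
    cornification, in genome assemblies. Delimits the locus between its
    flanking S100A marker genes, predicts short single-coding-exon (SEDC) and
    two-coding-exon (SFTP) genes de novo with TATA-box and splice-site
    evidence and pseudogene triage, profiles amino-acid composition and
    terminal transglutamination motifs, quantifies degenerate tandem repeats
    such as the avian EDCRP motif, validates expression by exact-match RNA-seq
    read counting against tissue transcriptomes, and infers cross-species
    orthology and Dollo gain/loss histories of EDC gene families. A seeded
    synthetic-locus generator with full ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
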