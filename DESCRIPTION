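Package: frankiapan
Title: Comparative Pangenomics of Host Specificity and Genome Reduction
    in Symbiotic Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative pangenome analysis of multi-strain
    bacterial panels, built around the inference chain used to study
    host specificity and symbiotic genome reduction in Alnus-infective
    Frankia. Provides an exact affine-gap Smith-Waterman/Needleman-Wunsch
    alignment core with BLOSUM62 scoring and Karlin-Altschul E-values,
    homologous protein family construction from all-vs-all local
    alignments (coverage and positive-score similarity thresholds,
    single-linkage components), core/pan/specific-core set algebra and
    group-wise lost-family detection over presence matrices,
    within-genome paralog detection and copy-number redundancy
    classification, COG and localization summaries of lost families,
    fragment-based average nucleotide identity with 95 percent species
    delineation, pairwise percent-identity matrices, a GC-content read
    contamination filter, and a seeded synthetic pangenome generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    igraph,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
NeedsCompilation: yes
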