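Package: srnadeg
Title: Small RNA and Degradome Sequencing Analysis for Plant miRNA Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for two-condition plant small
    RNA sequencing with degradome (PARE) support: read cleaning and
    length selection, collapsing to unique tags, hierarchical annotation
    against known mature miRNAs and noncoding RNA families, novel miRNA
    prediction from transcript-anchored hairpins folded with a reduced
    nearest-neighbour energy model, RPM normalisation with an exact
    tag-count test for differential expression, degradome-based cleavage
    site calling with t-plot categories 0-4, and 2^-ddCt qPCR
    quantification. A synthetic-data generator produces every input the
    pipeline consumes, with planted ground truth, so the whole analysis
    is reproducible without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
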