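Package: hybridEC
Title: Hybrid Error Correction of Noisy Long Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Corrects high-error long sequencing reads (PacBio/Nanopore) using
    alignments of accurate short reads. Implements consensus-based quick
    correction of questionable positions, optimization-based correction that
    selects the short read maximising a convex combination of normalised
    base-quality and alignment-identity weights, and an iterative learning
    loop that locks high-confidence corrections, realigns, and repeats until
    a k-mer based termination criterion fires. Ships a self-contained read
    simulator with truth tracking, k-mer and truth-alignment evaluation
    metrics, a built-in seed-and-extend banded aligner, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    Biostrings,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
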