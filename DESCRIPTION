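Package: papara
Title: Phylogeny-Aware Alignment of Short Reads Against Reference Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns short sequencing reads against every edge of a fixed
    reference phylogeny. For each edge a parsimony ancestral state vector
    and a per-site phylogenetic gap signal (CGAP) are computed from the
    reference alignment; each read is scored against each edge profile with
    a site-calibrated semi-global dynamic programming recurrence, the best
    edge per read is retained, and full alignments are backtracked for the
    winners only. Includes a portable re-expression of the inter-reference
    batch layout (W references interleaved site-major), 5-bit state packing
    (6 elements per 32-bit word), and a blocked column schedule, all
    bit-exact against the sequential kernel, plus a synthetic data
    generator for trees, gapped reference alignments and error-bearing
    reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
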