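Package: memtax
Title: Taxonomic Read Classification with Maximal Exact Matches over
    Kernelized and Minimizer-Digested Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds augmented FM-indexes (suffix array, Burrows-Wheeler
    transform with rank support, LCP array with previous/next-smaller-value
    queries, and a document-boundary bitvector) over a concatenated
    collection of reference genomes and over three lossily compressed
    representations of it: an order-kmax string kernel that keeps only the
    first and last occurrence of every distinct kmax-mer, a minimizer
    digest, and a kernel of a minimizer digest. Computes per-read MEM
    (maximal exact match) tables by right-to-left matching-statistics
    computation with LCP-based contraction, maps each MEM to its first and
    last genome of occurrence and the corresponding lowest-common-ancestor
    subtree of a taxonomy, and evaluates true-positive rates on simulated
    reads to chart the compression/accuracy trade-off.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
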