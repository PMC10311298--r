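Package: lpmphf
Title: Locality-Preserving Minimal Perfect Hashing of k-mers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build and query locality-preserving minimal perfect hash
    functions (LP-MPHFs) for the distinct k-mers of a spectrum-preserving
    string set (SPSS). The construction decomposes the input strings into
    super-k-mers under a seeded random minimizer scheme and ranks k-mers
    implicitly through the minimizer position, so that consecutive k-mers
    receive consecutive hash codes for most positions. Two memory layouts
    are provided: an unpartitioned layout storing per-minimizer prefix sums
    and positions, and a partitioned layout that classifies super-k-mers by
    the first/last minimizer-position rule and drops redundant entries.
    Includes succinct building blocks (rank-supported bitvectors, Elias-Fano
    sequences, a 4-symbol wavelet tree), a generic multi-level minimal
    perfect hash function, closed-form expectations for minimizer density
    and super-k-mer type probabilities, empirical measurement tools, a
    synthetic SPSS generator, FASTA input/output, and index serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    Biostrings,
    BiocGenerics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
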