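#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Number of distinct k-mers
#'
#' @param x an [Spss-class] or [LpMphf-class] object.
#' @return A single number: the total count of distinct k-mers.
#' @export
setGeneric("nKmers", function(x) standardGeneric("nKmers"))

#' k-mer length of an object
#'
#' @param x a [MinimizerScheme-class], [Spss-class] or [LpMphf-class] object.
#' @return The k-mer length k.
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))

#' Minimizer length of a scheme or index
#'
#' @param x a [MinimizerScheme-class] or [LpMphf-class] object.
#' @return The minimizer length m.
#' @export
setGeneric("minimizerLength", function(x) standardGeneric("minimizerLength"))

#' Window count w = k - m + 1
#'
#' @param x a [MinimizerScheme-class] or [LpMphf-class] object.
#' @return The number of m-mer windows per k-mer.
#' @export
setGeneric("windowCount", function(x) standardGeneric("windowCount"))

#' Look up k-mers in an LP-MPHF index
#'
#' Evaluates the hash function on each k-mer independently (the "random"
#' query modality).  Restricted to the indexed spectrum the result is a
#' bijection onto \code{0..nKmers(x)-1}.
#'
#' @param x an [LpMphf-class] index.
#' @param kmers character vector of k-mers (A,C,G,T; length k each).
#' @param strict if \code{TRUE}, return \code{NA} for k-mers whose implied
#'   in-super-k-mer rank falls outside the stored super-k-mer (a detectable
#'   non-member); note an MPHF is not a membership structure, so alien
#'   k-mers may still receive an in-range code.
#' @return Numeric vector of 0-based codes (or \code{NA} under
#'   \code{strict} when detectably absent).
#' @export
setGeneric("lookupKmers", function(x, kmers, strict = FALSE)
    standardGeneric("lookupKmers"))

#' Stream all k-mers of sequences through an LP-MPHF index
#'
#' Computes one code per k-mer of each query sequence, sliding a minimizer
#' window so the per-minimizer slot is resolved once per super-k-mer run
#' instead of once per k-mer.  Output is elementwise identical to
#' [lookupKmers()] applied to every k-mer.
#'
#' @param x an [LpMphf-class] index.
#' @param sequences character vector (or [Spss-class]) of query sequences,
#'   each of length >= k.
#' @param strict as in [lookupKmers()].
#' @return A list with one numeric code vector per sequence (a single
#'   vector if one sequence was given).
#' @export
setGeneric("lookupStreaming", function(x, sequences, strict = FALSE)
    standardGeneric("lookupStreaming"))

#' Space accounting of a succinct structure or index
#'
#' @param x a [RankBitVector-class], [EliasFanoSeq-class],
#'   [WaveletTree4-class], [Mphf-class] or [LpMphf-class] object.
#' @return A list of bit counts; for indexes, per-component bits and
#'   \code{bitsPerKmer}.
#' @export
setGeneric("spaceReport", function(x) standardGeneric("spaceReport"))

#' Serialize an LP-MPHF index to a file
#'
#' The on-disk format is the little-endian byte stream produced at build
#' time: magic bytes "LPMH", a version number, the layout flag, the scheme
#' (k, m, seed) and the length-prefixed components.
#'
#' @param x an [LpMphf-class] index.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @seealso [loadIndex()]
#' @export
setGeneric("saveIndex", function(x, path) standardGeneric("saveIndex"))
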