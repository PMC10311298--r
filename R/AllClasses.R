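#' MinimizerScheme: a (k, m, seed) random minimizer scheme
#'
#' A random minimizer scheme selects, inside every k-mer, the m-mer with the
#' smallest value under a seeded 64-bit random hash \code{h}; ties are broken
#' towards the leftmost m-mer.  The derived window count \code{w = k - m + 1}
#' is the number of candidate m-mers per k-mer.
#'
#' @slot k k-mer length (symbols).
#' @slot m minimizer length (symbols), with \code{1 <= m <= k}.
#' @slot seed non-negative integer seeding the random hash \code{h}.
#'
#' @seealso [minimizerScheme()] for the validating constructor.
#' @name MinimizerScheme-class
#' @rdname MinimizerScheme-class
#' @exportClass MinimizerScheme
setClass("MinimizerScheme",
    representation(k = "integer", m = "integer", seed = "numeric"))

setValidity("MinimizerScheme", function(object) {
    msgs <- character()
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
        msgs <- c(msgs, "k must be a single positive integer")
    if (length(object@m) != 1L || is.na(object@m) || object@m < 1L)
        msgs <- c(msgs, "m must be a single positive integer")
    if (length(msgs) == 0L && object@m > object@k)
        msgs <- c(msgs, "m must not exceed k (need 1 <= m <= k, so that w >= 1)")
    if (length(object@seed) != 1L || is.na(object@seed) || object@seed < 0 ||
        object@seed != floor(object@seed))
        msgs <- c(msgs, "seed must be a single non-negative integer")
    if (length(msgs)) msgs else TRUE
})

#' Construct a random minimizer scheme
#'
#' @param k k-mer length.
#' @param m minimizer length, \code{1 <= m <= k}.
#' @param seed non-negative integer seed for the random m-mer hash.
#'
#' @details
#' A warning (not an error) is emitted when \code{m <= (3 + 0.001) *
#' log4(w + 1)}: below that regime the expected minimizer density
#' \code{2 / (w + 1)} (see [expectedDensity()]) is not guaranteed by theory,
#' and minimizers of such short length are typically shared by many k-mers.
#'
#' @return A [MinimizerScheme-class] object.
#' @examples
#' sc <- minimizerScheme(k = 31, m = 21, seed = 1)
#' windowCount(sc) # 11
#' @export
minimizerScheme <- function(k, m, seed = 1) {
    sc <- new("MinimizerScheme", k = as.integer(k), m = as.integer(m),
              seed = as.numeric(seed))
    validObject(sc)
    w <- sc@k - sc@m + 1L
    if (sc@m <= (3 + 0.001) * log(w + 1, base = 4))
        warning("m = ", sc@m, " is at or below (3+eps)*log4(w+1) = ",
                format((3 + 0.001) * log(w + 1, base = 4), digits = 4),
                "; the 2/(w+1) density regime does not apply", call. = FALSE)
    sc
}

#' Spss: a spectrum-preserving string set
#'
#' An ordered set of DNA strings (alphabet A, C, G, T) in which every k-mer
#' occurs exactly once across all strings, together with the k it was
#' validated for.  This is the input of the LP-MPHF construction.
#'
#' @slot sequences a [Biostrings::DNAStringSet] with the strings, in order;
#'   names carry the original record identifiers.
#' @slot k the k-mer length the set was validated for.
#' @slot n total number of (distinct) k-mers.
#'
#' @seealso [readSpss()], [syntheticSpss()], [writeSpss()].
#' @name Spss-class
#' @rdname Spss-class
#' @exportClass Spss
setClass("Spss",
    representation(sequences = "DNAStringSet", k = "integer", n = "numeric"))

setValidity("Spss", function(object) {
    if (length(object@sequences) == 0L) return("SPSS must contain at least one string")
    widths <- BiocGenerics::width(object@sequences)
    if (any(widths < object@k))
        return("every SPSS string must have length >= k")
    if (object@n != sum(widths - object@k + 1))
        return("n must equal the total k-mer count of the strings")
    TRUE
})

#' RankBitVector: a bitvector with constant-time rank support
#'
#' Stores N bits plus absolute rank counters sampled every 512 bits, so that
#' \code{rank1(i)} (number of set bits among the first i) is answered exactly
#' in constant time.
#'
#' @slot bytes serialized payload (little-endian 64-bit words).
#' @slot n number of bits.
#' @seealso [rankBitVector()], [bvRank1()].
#' @name RankBitVector-class
#' @rdname RankBitVector-class
#' @exportClass RankBitVector
setClass("RankBitVector", representation(bytes = "raw", n = "numeric"))

#' EliasFanoSeq: Elias-Fano encoded monotone sequence
#'
#' Succinct representation of a non-decreasing sequence of non-negative
#' integers with exact constant-time random access.
#'
#' @slot bytes serialized encoding (low bits + high-part bitvector).
#' @slot n number of elements.
#' @slot universe the largest encoded value.
#' @seealso [eliasFano()], [efAccess()].
#' @name EliasFanoSeq-class
#' @rdname EliasFanoSeq-class
#' @exportClass EliasFanoSeq
setClass("EliasFanoSeq",
    representation(bytes = "raw", n = "numeric", universe = "numeric"))

#' WaveletTree4: succinct sequence over a 4-symbol alphabet
#'
#' Two-level wavelet tree over symbols \{0,1,2,3\} (2 bits per symbol payload)
#' supporting \code{access(i)} and per-symbol prefix rank \code{rank_t(i)} in
#' constant time.  Used by the partitioned index to store super-k-mer types.
#'
#' @slot bytes serialized layers.
#' @slot n sequence length.
#' @seealso [waveletTree4()], [wtAccess()], [wtRank()].
#' @name WaveletTree4-class
#' @rdname WaveletTree4-class
#' @exportClass WaveletTree4
setClass("WaveletTree4", representation(bytes = "raw", n = "numeric"))

#' Mphf: a generic minimal perfect hash function
#'
#' Maps n distinct byte-string keys bijectively onto the codes 0..n-1.
#' Built with multi-level collision-cascading bitmaps; keys outside the
#' construction set evaluate to an arbitrary (but deterministic) in-range
#' value.  Used for the minimizer function f_m and the fallback MPHF of the
#' LP-MPHF, and available on its own.
#'
#' @slot bytes serialized levels, seed and remainder table.
#' @slot n number of keys.
#' @slot seed master seed.
#' @seealso [mphfBuild()], [mphfEval()].
#' @name Mphf-class
#' @rdname Mphf-class
#' @exportClass Mphf
setClass("Mphf", representation(bytes = "raw", n = "numeric", seed = "numeric"))

#' LpMphf: locality-preserving minimal perfect hash index over an SPSS
#'
#' Virtual parent of the two concrete layouts.  An LP-MPHF maps the n
#' distinct k-mers of an SPSS bijectively onto 0..n-1 such that consecutive
#' k-mers of a string receive consecutive codes for a (1 - eps) fraction of
#' positions.  K-mers of unambiguous minimizers occupy codes
#' \code{[0, nUnambiguous)}; k-mers whose minimizer is shared by more than
#' one super-k-mer are routed to a fallback MPHF occupying the tail.
#'
#' @slot bytes the serialized index (the on-disk format, see [saveIndex()]).
#' @slot scheme the [MinimizerScheme-class] used at build time.
#' @slot n total distinct k-mers.
#' @slot nUnambiguous k-mers covered by unambiguous minimizers.
#' @slot nMinimizers number of distinct minimizers.
#'
#' @seealso [lpMphf()], [lookupKmers()], [lookupStreaming()], [spaceReport()].
#' @name LpMphf-class
#' @rdname LpMphf-class
#' @exportClass LpMphf
setClass("LpMphf",
    representation(bytes = "raw", scheme = "MinimizerScheme", n = "numeric",
                   nUnambiguous = "numeric", nMinimizers = "numeric", "VIRTUAL"))

#' @rdname LpMphf-class
#' @exportClass UnpartitionedLpMphf
setClass("UnpartitionedLpMphf", contains = "LpMphf")

#' @rdname LpMphf-class
#' @exportClass PartitionedLpMphf
setClass("PartitionedLpMphf", contains = "LpMphf")
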