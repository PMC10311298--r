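#' Build a locality-preserving MPHF over an SPSS
#'
#' One pass decomposes the strings into super-k-mers under the minimizer
#' scheme; a minimizer shared by more than one super-k-mer is
#' \emph{ambiguous} and its k-mers are routed to a fallback MPHF occupying
#' the tail of the codomain, while each unambiguous minimizer contributes
#' one slot holding its super-k-mer's size and first-k-mer minimizer
#' position.  Lookup of a k-mer x computes its minimizer (value and 1-based
#' position p), resolves the slot through the minimizer MPHF f_m, and
#' returns the slot's code base plus the implicit in-super-k-mer rank
#' \code{p1 - p}, so consecutive k-mers of a super-k-mer receive
#' consecutive codes.
#'
#' Two layouts are available.  The \emph{unpartitioned} layout stores a
#' prefix-sum array L (Elias-Fano) and a position array P over all slots.
#' The \emph{partitioned} layout classifies each slot by the first/last
#' rule into left-right-max / left-max / right-max / non-max, stores the
#' types in a 4-symbol wavelet tree, and then drops everything that the
#' type makes redundant: left-right-max slots need no storage at all
#' (size = p1 = w), left/right-max slots store only their size prefix sums,
#' and only non-max slots keep an explicit position.  Ambiguous slots are
#' typed right-max with a size-0 sentinel.  Both layouts are minimal
#' perfect over the same spectrum; their codes differ by a per-partition
#' permutation.
#'
#' @param spss an [Spss-class] (validated SPSS).
#' @param scheme a [MinimizerScheme-class]; its k must equal the Spss's k.
#' @param layout \code{"partitioned"} (default) or \code{"unpartitioned"}.
#' @return An [LpMphf-class] index (subclass per layout).
#' @examples
#' s <- syntheticSpss(2000, k = 31, seed = 5)
#' ix <- lpMphf(s, minimizerScheme(31, 15, seed = 5))
#' codes <- lookupStreaming(ix, s)
#' setequal(codes, 0:1999)
#' @export
lpMphf <- function(spss, scheme, layout = c("partitioned", "unpartitioned")) {
    stopifnot(is(spss, "Spss"), is(scheme, "MinimizerScheme"))
    layout <- match.arg(layout)
    if (scheme@k != spss@k)
        stop("scheme k (", scheme@k, ") differs from SPSS k (", spss@k, ")")
    bytes <- cpp_index_build(as.character(spss@sequences), scheme@k, scheme@m,
                             scheme@seed, layout == "partitioned")
    info <- cpp_index_info(bytes)
    cls <- if (layout == "partitioned") "PartitionedLpMphf" else "UnpartitionedLpMphf"
    new(cls, bytes = bytes, scheme = scheme, n = info$n,
        nUnambiguous = info$nUnambiguous, nMinimizers = info$nMinimizers)
}

#' @rdname lookupKmers
#' @export
setMethod("lookupKmers", "LpMphf", function(x, kmers, strict = FALSE) {
    cpp_index_lookup(x@bytes, as.character(kmers), isTRUE(strict))
})

#' @rdname lookupStreaming
#' @export
setMethod("lookupStreaming", "LpMphf", function(x, sequences, strict = FALSE) {
    seqs <- if (is(sequences, "Spss")) as.character(sequences@sequences)
            else as.character(sequences)
    out <- cpp_index_stream(x@bytes, seqs, isTRUE(strict))
    if (length(out) == 1L) out[[1L]] else out
})

#' @rdname nKmers
#' @export
setMethod("nKmers", "LpMphf", function(x) x@n)

#' @rdname kmerLength
#' @export
setMethod("kmerLength", "LpMphf", function(x) x@scheme@k)

#' @rdname minimizerLength
#' @export
setMethod("minimizerLength", "LpMphf", function(x) x@scheme@m)

#' @rdname windowCount
#' @export
setMethod("windowCount", "LpMphf", function(x) windowCount(x@scheme))

#' Layout name of an index
#'
#' @param x an [LpMphf-class].
#' @return \code{"partitioned"} or \code{"unpartitioned"}.
#' @export
indexLayout <- function(x) {
    if (is(x, "PartitionedLpMphf")) "partitioned" else "unpartitioned"
}

#' Full description of an index
#'
#' @param x an [LpMphf-class].
#' @return A list with layout, scheme parameters, k-mer counts (total,
#'   unambiguous, fallback), minimizer count, per-partition k-mer totals
#'   and slot counts (partitioned layout), per-component bit counts and
#'   bits per k-mer.
#' @export
indexInfo <- function(x) {
    stopifnot(is(x, "LpMphf"))
    cpp_index_info(x@bytes)
}

#' Decoded layout arrays of an index
#'
#' White-box accessor for inspection and testing.  For the unpartitioned
#' layout, returns the prefix-sum array \code{L} (length |M|+1, leading 0)
#' and position array \code{P}.  For the partitioned layout, the slot type
#' codes (0 = left-right-max, 1 = left-max, 2 = right-max, 3 = non-max) and
#' the per-type prefix sums \code{Ll}, \code{Lr}, \code{Ln} and positions
#' \code{Pn}.
#'
#' @param x an [LpMphf-class].
#' @return A list of numeric vectors.
#' @export
indexComponents <- function(x) {
    stopifnot(is(x, "LpMphf"))
    cpp_index_components(x@bytes)
}

#' @rdname spaceReport
#' @export
setMethod("spaceReport", "LpMphf", function(x) {
    info <- cpp_index_info(x@bytes)
    c(info$bits, list(bitsPerKmer = info$bitsPerKmer, n = info$n))
})

setMethod("show", "LpMphf", function(object) {
    info <- cpp_index_info(object@bytes)
    cat(sep = "", class(object), " (", info$layout, "): ",
        format(info$n, big.mark = ","), " k-mers (k=", info$k, ", m=", info$m,
        ", w=", info$w, ", seed=", info$seed, ")\n",
        "  minimizers: ", format(info$nMinimizers, big.mark = ","),
        "; fallback k-mers: ", format(info$nFallback, big.mark = ","),
        " (xi = ", format(info$nFallback / info$n, digits = 3), ")\n",
        "  space: ", format(info$bitsPerKmer, digits = 4), " bits/k-mer\n")
})

#' @rdname saveIndex
#' @export
setMethod("saveIndex", "LpMphf", function(x, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(x@bytes, con)
    invisible(path)
})

#' Load an LP-MPHF index from a file
#'
#' Checks the magic bytes, format version and component lengths; a
#' truncated or corrupted file raises a format error naming the offending
#' byte offset.
#'
#' @param path a file written by [saveIndex()].
#' @return An [LpMphf-class] index answering lookups identically to the
#'   saved one.
#' @export
loadIndex <- function(path) {
    bytes <- readBin(path, "raw", n = file.size(path))
    info <- cpp_index_info(bytes) # validates magic, version, structure
    scheme <- new("MinimizerScheme", k = as.integer(info$k),
                  m = as.integer(info$m), seed = as.numeric(info$seed))
    cls <- if (info$layout == "partitioned") "PartitionedLpMphf" else "UnpartitionedLpMphf"
    new(cls, bytes = bytes, scheme = scheme, n = info$n,
        nUnambiguous = info$nUnambiguous, nMinimizers = info$nMinimizers)
}
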