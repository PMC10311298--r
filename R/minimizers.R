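#' @rdname windowCount
#' @export
setMethod("windowCount", "MinimizerScheme", function(x) x@k - x@m + 1L)

#' @rdname kmerLength
#' @export
setMethod("kmerLength", "MinimizerScheme", function(x) x@k)

#' @rdname minimizerLength
#' @export
setMethod("minimizerLength", "MinimizerScheme", function(x) x@m)

setMethod("show", "MinimizerScheme", function(object) {
    cat("MinimizerScheme: k =", object@k, ", m =", object@m,
        ", w =", object@k - object@m + 1L, ", seed =", object@seed, "\n")
})

flTypeNames <- c("left-right-max", "left-max", "right-max", "non-max")

#' Hash m-mers with the scheme's random hash
#'
#' Exposes the seeded 64-bit hash \code{h} applied to the ASCII bytes of an
#' m-mer, as a 16-digit lower-case hexadecimal string (so that values can be
#' compared exactly in R, which has no native 64-bit integers; lexicographic
#' order on the fixed-width hex strings equals numeric order).
#'
#' @param mmers character vector of m-mers.
#' @param scheme a [MinimizerScheme-class] (only the seed is used).
#' @return Character vector of hex-encoded 64-bit hash values.
#' @export
mmerHash <- function(mmers, scheme) {
    cpp_mmer_hash(as.character(mmers), scheme@seed)
}

#' Minimizer of a k-mer
#'
#' The minimizer of a k-mer x is the m-mer with minimal hash among the
#' \code{w = k - m + 1} m-mers of x; ties are broken towards the leftmost
#' occurrence.
#'
#' @param kmers character vector of k-mers, each of length \code{kmerLength(scheme)}.
#' @param scheme a [MinimizerScheme-class].
#' @return A data.frame with one row per k-mer: \code{mmer} (the minimizer),
#'   \code{pos} (its 1-based start position within the k-mer, in
#'   \code{1..w}), and \code{hash} (hex-encoded hash value).
#' @examples
#' sc <- minimizerScheme(31, 21, seed = 7)
#' minimizerOfKmer(paste(rep("A", 31), collapse = ""), sc)$pos # 1 (all-tie)
#' @export
minimizerOfKmer <- function(kmers, scheme) {
    res <- cpp_minimizer_of_kmer(as.character(kmers), scheme@k, scheme@m, scheme@seed)
    data.frame(mmer = res$mmer, pos = res$pos, hash = res$hash,
               stringsAsFactors = FALSE)
}

#' Minimizers of all k-mers of a sequence
#'
#' Slides a monotone-queue minimum over the m-mer hashes so each position is
#' hashed once (amortized constant work per k-mer); the result is elementwise
#' identical to calling [minimizerOfKmer()] on every k-mer.
#'
#' @param sequence a single string of length >= k.
#' @param scheme a [MinimizerScheme-class].
#' @return A data.frame with one row per k-mer: \code{mmer}, \code{pos}
#'   (1-based within the k-mer), \code{absPos} (0-based start of the chosen
#'   minimizer occurrence in the sequence), \code{hash}.
#' @export
streamingMinimizers <- function(sequence, scheme) {
    stopifnot(length(sequence) == 1L)
    res <- cpp_streaming_minimizers(as.character(sequence), scheme@k, scheme@m,
                                    scheme@seed)
    data.frame(mmer = res$mmer, pos = res$pos, absPos = res$absPos,
               hash = res$hash, stringsAsFactors = FALSE)
}

#' Super-k-mer decomposition of sequences
#'
#' A super-k-mer is a maximal run of consecutive k-mers selecting the same
#' minimizer occurrence (the same m-mer at the same absolute position).  The
#' super-k-mers of a string partition its k-mers in order.  A new super-k-mer
#' starts when the minimizer value changes or when the same value is selected
#' at a new absolute position.
#'
#' @param x a character vector of sequences or an [Spss-class].
#' @param scheme a [MinimizerScheme-class].
#' @return A data.frame with one row per super-k-mer: \code{stringId}
#'   (1-based source string), \code{start} (0-based offset of the first
#'   symbol), \code{length} (symbols), \code{size} (k-mers, = length-k+1),
#'   \code{minimizer}, \code{pFirst}, \code{pLast} (1-based minimizer start
#'   in the first/last k-mer), and \code{flType} (factor with levels
#'   left-right-max, left-max, right-max, non-max).
#' @examples
#' sc <- minimizerScheme(13, 7, seed = 3)
#' g <- superKmers(syntheticSpss(50, k = 13, seed = 11), sc)
#' all(g$size <= g$pFirst & g$pFirst <= windowCount(sc))
#' @export
superKmers <- function(x, scheme) {
    seqs <- if (is(x, "Spss")) as.character(x@sequences) else as.character(x)
    out <- lapply(seq_along(seqs), function(i) {
        res <- cpp_superkmers(seqs[[i]], i - 1, scheme@k, scheme@m, scheme@seed)
        data.frame(stringId = i, start = res$start, length = res$length,
                   size = res$size, minimizer = res$minimizer,
                   pFirst = res$pFirst, pLast = res$pLast,
                   flType = factor(flTypeNames[res$flType + 1L],
                                   levels = flTypeNames),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Rank of a k-mer inside a super-k-mer
#'
#' Given the 1-based minimizer position \code{p} observed in a query k-mer
#' and a super-k-mer whose first k-mer has minimizer position \code{pFirst}
#' and which spans \code{size} k-mers, the k-mer's rank inside the
#' super-k-mer is \code{pFirst - p + 1}.  When that value falls outside
#' \code{1..size} the k-mer cannot belong to the super-k-mer and \code{NA}
#' is returned.
#'
#' @param p 1-based minimizer position in the query k-mer.
#' @param pFirst 1-based minimizer position in the super-k-mer's first k-mer.
#' @param size number of k-mers in the super-k-mer.
#' @return Integer rank in \code{1..size}, or \code{NA} (out of range).
#' @examples
#' rankInSuperKmer(5:3, pFirst = 5, size = 3) # 1 2 3
#' rankInSuperKmer(2, pFirst = 5, size = 3)   # NA
#' @export
rankInSuperKmer <- function(p, pFirst, size) {
    n <- max(length(p), length(pFirst), length(size))
    p <- rep_len(as.integer(p), n)
    pFirst <- rep_len(as.integer(pFirst), n)
    size <- rep_len(as.integer(size), n)
    stopifnot(all(size >= 1L), all(size <= pFirst))
    r <- pFirst - p + 1L
    r[r < 1L | r > size] <- NA_integer_
    r
}

#' Classify a super-k-mer by the first/last (FL) rule
#'
#' A super-k-mer is \emph{left-right-max} when the minimizer starts at the
#' maximal position w in its first k-mer and at position 1 in its last
#' k-mer; \emph{left-max} when only the last condition holds;
#' \emph{right-max} when only the first holds; \emph{non-max} otherwise.
#' The four types partition all super-k-mers.
#'
#' @param pFirst 1-based minimizer position in the first k-mer.
#' @param pLast 1-based minimizer position in the last k-mer.
#' @param w window count of the scheme.
#' @return Factor with levels left-right-max, left-max, right-max, non-max.
#' @examples
#' classifySuperKmer(c(7, 5, 7, 4), c(1, 1, 3, 2), w = 7)
#' @export
classifySuperKmer <- function(pFirst, pLast, w) {
    n <- max(length(pFirst), length(pLast))
    pFirst <- rep_len(as.integer(pFirst), n)
    pLast <- rep_len(as.integer(pLast), n)
    if (any(pLast < 1L | pFirst > w | pLast > pFirst))
        stop("need 1 <= pLast <= pFirst <= w")
    type <- ifelse(pFirst == w,
                   ifelse(pLast == 1L, "left-right-max", "right-max"),
                   ifelse(pLast == 1L, "left-max", "non-max"))
    factor(type, levels = flTypeNames)
}
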