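#' Build a rank-supported bitvector
#'
#' @param bits logical or 0/1 integer vector.
#' @return A [RankBitVector-class].
#' @examples
#' bv <- rankBitVector(c(1, 0, 1, 1))
#' bvRank1(bv, 0:4) # 0 1 1 2 3
#' @export
rankBitVector <- function(bits) {
    bits <- as.integer(bits)
    new("RankBitVector", bytes = cpp_bv_build(bits), n = as.numeric(length(bits)))
}

#' Rank query on a bitvector
#'
#' \code{bvRank1(bv, i)} counts the set bits among the first \code{i} bits
#' (prefix semantics: \code{i} ranges over \code{0..N}, \code{bvRank1(bv, 0)
#' == 0} and \code{bvRank1(bv, N)} is the total number of ones).
#'
#' @param bv a [RankBitVector-class].
#' @param i prefix length(s), each in \code{0..N}.
#' @return Numeric vector of counts.
#' @export
bvRank1 <- function(bv, i) {
    stopifnot(is(bv, "RankBitVector"))
    cpp_bv_rank1(bv@bytes, as.numeric(i))
}

setMethod("show", "RankBitVector", function(object) {
    info <- cpp_bv_info(object@bytes)
    cat("RankBitVector:", info$n, "bits,", info$ones, "set,",
        info$bitsTotal, "bits total\n")
})

#' @rdname spaceReport
#' @export
setMethod("spaceReport", "RankBitVector", function(x) cpp_bv_info(x@bytes))

#' Elias-Fano encode a monotone sequence
#'
#' @param values non-decreasing vector of non-negative integers.
#' @return An [EliasFanoSeq-class].
#' @examples
#' ef <- eliasFano(c(0, 0, 0, 5, 5, 9))
#' efAccess(ef, 1:6) # round-trips exactly
#' @export
eliasFano <- function(values) {
    values <- as.numeric(values)
    if (length(values) == 0L) stop("cannot encode an empty sequence")
    bytes <- cpp_ef_encode(values)
    new("EliasFanoSeq", bytes = bytes, n = length(values),
        universe = values[length(values)])
}

#' Access an element of an Elias-Fano sequence
#'
#' @param ef an [EliasFanoSeq-class].
#' @param i 1-based element index (vectorized), in \code{1..n}.
#' @return Numeric vector of the decoded values (exact).
#' @export
efAccess <- function(ef, i) {
    stopifnot(is(ef, "EliasFanoSeq"))
    i <- as.numeric(i)
    if (any(i < 1 | i > ef@n)) stop("index out of range 1..", ef@n)
    cpp_ef_access(ef@bytes, i - 1)
}

setMethod("show", "EliasFanoSeq", function(object) {
    info <- cpp_ef_info(object@bytes)
    cat("EliasFanoSeq:", info$n, "values over universe [0,", info$universe,
        "],", info$lowWidth, "low bits,", info$bitsTotal, "bits total\n")
})

#' @rdname spaceReport
#' @export
setMethod("spaceReport", "EliasFanoSeq", function(x) cpp_ef_info(x@bytes))

#' Build a 4-symbol wavelet tree
#'
#' @param symbols vector of integers in \code{0..3}.
#' @return A [WaveletTree4-class].
#' @examples
#' wt <- waveletTree4(c(0, 1, 2, 3, 0, 1, 2, 3))
#' wtRank(wt, 3, 8) # 2
#' @export
waveletTree4 <- function(symbols) {
    symbols <- as.integer(symbols)
    if (length(symbols) == 0L) stop("cannot build a wavelet tree over an empty sequence")
    new("WaveletTree4", bytes = cpp_wt_build(symbols), n = length(symbols))
}

#' Access a wavelet tree position
#'
#' @param wt a [WaveletTree4-class].
#' @param i 1-based position(s) in \code{1..n}.
#' @return Integer symbol(s) in \code{0..3}.
#' @export
wtAccess <- function(wt, i) {
    stopifnot(is(wt, "WaveletTree4"))
    i <- as.numeric(i)
    if (any(i < 1 | i > wt@n)) stop("index out of range 1..", wt@n)
    cpp_wt_access(wt@bytes, i - 1)
}

#' Per-symbol prefix rank on a wavelet tree
#'
#' \code{wtRank(wt, t, i)} counts the occurrences of symbol \code{t} in the
#' prefix of length \code{i} (positions 1..i); \code{i = 0} is allowed and
#' yields 0.
#'
#' @param wt a [WaveletTree4-class].
#' @param t symbol(s) in \code{0..3}.
#' @param i prefix length(s) in \code{0..n}.
#' @return Numeric vector of counts.
#' @export
wtRank <- function(wt, t, i) {
    stopifnot(is(wt, "WaveletTree4"))
    n <- max(length(t), length(i))
    t <- rep_len(as.integer(t), n)
    i <- rep_len(as.numeric(i), n)
    if (any(i < 0 | i > wt@n)) stop("prefix length out of range 0..", wt@n)
    cpp_wt_rank(wt@bytes, t, i)
}

setMethod("show", "WaveletTree4", function(object) {
    info <- cpp_wt_info(object@bytes)
    cat("WaveletTree4:", info$n, "symbols,", info$bitsTotal, "bits total (",
        format(info$bitsTotal / info$n, digits = 3), "bits/symbol )\n")
})

#' @rdname spaceReport
#' @export
setMethod("spaceReport", "WaveletTree4", function(x) cpp_wt_info(x@bytes))
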