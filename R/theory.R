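#' Expected super-k-mer density of a random minimizer scheme
#'
#' For a random minimizer scheme with window count \code{w = k - m + 1} and
#' \code{m} large enough (above \code{(3+eps)*log4(w+1)}), the expected
#' number of super-k-mers per k-mer is \code{2 / (w + 1)}, lower-order
#' terms dropped.  This is also the expected locality-preservation defect
#' eps of the index built on a single-string SPSS (up to the fragmentation
#' and ambiguity corrections).
#'
#' @param w window count, \code{w >= 1}.
#' @return \code{2 / (w + 1)}.
#' @examples
#' expectedDensity(1)  # 1: every k-mer starts its own super-k-mer
#' expectedDensity(11) # 1/6
#' @export
expectedDensity <- function(w) {
    if (any(w < 1)) stop("w must be >= 1")
    2 / (w + 1)
}

#' Closed-form super-k-mer type probabilities
#'
#' Probabilities that a super-k-mer of a random minimizer scheme is
#' left-right-max, left-max, right-max or non-max under the first/last
#' rule, as functions of the window count alone:
#' with \code{W = (1 - 1/w) / 2},
#' \deqn{P_{lr} = W^2 + 1/w, \quad P_l = P_r = W (1 - W), \quad P_n = W^2.}
#' The four probabilities sum to one (the rule is a partition), the left-
#' and right-max probabilities are equal, and \code{P_lr - P_n = 1/w}.
#' For \code{w = 1} every super-k-mer is a single k-mer whose minimizer
#' position is both maximal and minimal, so the distribution degenerates
#' to \code{(1, 0, 0, 0)}.
#'
#' @param w window count, \code{w >= 1}.
#' @return Named numeric vector \code{c(lr, l, r, n)}.
#' @examples
#' round(flTypeProbabilities(11), 3) # k=31, m=21
#' @export
flTypeProbabilities <- function(w) {
    if (length(w) != 1 || w < 1) stop("w must be a single value >= 1")
    if (w == 1) return(c(lr = 1, l = 0, r = 0, n = 0))
    W <- (1 - 1 / w) / 2
    c(lr = W^2 + 1 / w, l = W * (1 - W), r = W * (1 - W), n = W^2)
}

#' Space bound of the unpartitioned layout
#'
#' The unpartitioned index over n k-mers with window count w and an inner
#' MPHF costing b bits per key takes at most
#' \deqn{n \cdot \frac{2}{w+1}\left(\log_2(4 (w+1)^2) + b + o(1)\right)}
#' bits; the vanishing term is represented by a single constant
#' \code{overhead} (default 0.5, matching the rank-directory overhead of
#' the practical structures).  The bound divided by n decreases as w grows.
#'
#' @param n number of k-mers.
#' @param w window count.
#' @param b bits per key of the inner MPHF; must exceed \code{log2(e)}
#'   (about 1.443), the information-theoretic MPHF minimum.
#' @param overhead the lower-order term estimate (default 0.5).
#' @return Total bits (not bits per k-mer).
#' @examples
#' spaceBound(1e6, 11, b = 2.5) / 1e6 # bits per k-mer
#' @export
spaceBound <- function(n, w, b, overhead = 0.5) {
    if (any(n < 1) || any(w < 1)) stop("need n >= 1 and w >= 1")
    if (any(b <= log2(exp(1))))
        stop("b must exceed log2(e) = ", format(log2(exp(1)), digits = 6),
             " bits/key (information-theoretic MPHF minimum)")
    n * (2 / (w + 1)) * (log2(4 * (w + 1)^2) + b + overhead)
}

#' Expected scheme statistics
#'
#' Closed-form expectations for a scheme or window count: density,
#' expected locality defect, and type probabilities.
#'
#' @param x a [MinimizerScheme-class] or a window count w.
#' @return A list with \code{w}, \code{density}, \code{epsExpected}
#'   (\code{= 2/(w+1)}), \code{W}, and \code{typeProbabilities}.
#' @export
schemeStats <- function(x) {
    w <- if (is(x, "MinimizerScheme")) windowCount(x) else as.numeric(x)
    list(w = w, density = expectedDensity(w), epsExpected = expectedDensity(w),
         W = (1 - 1 / w) / 2, typeProbabilities = flTypeProbabilities(w))
}

#' Measure super-k-mer statistics of an SPSS under a scheme
#'
#' Decomposes every string and reports the measured counterparts of the
#' closed-form quantities: k-mer and super-k-mer counts, the measured
#' density, the fragmentation factor alpha, the ambiguous-minimizer
#' statistics (xi = fraction of k-mers whose minimizer is shared by more
#' than one super-k-mer), and the first/last-rule type fractions among
#' unambiguous super-k-mers.
#'
#' @param spss an [Spss-class].
#' @param scheme a [MinimizerScheme-class].
#' @param index optionally, an [LpMphf-class] built from the same inputs;
#'   its space report is then included.
#' @return A list; \code{typeFractions} sums to 1 over unambiguous
#'   super-k-mers.
#' @examples
#' s <- syntheticSpss(5000, 31, seed = 3)
#' st <- measureScheme(s, minimizerScheme(31, 21, seed = 3))
#' abs(st$density - expectedDensity(11)) < 0.05
#' @export
measureScheme <- function(spss, scheme, index = NULL) {
    stopifnot(is(spss, "Spss"), is(scheme, "MinimizerScheme"))
    res <- cpp_measure_scheme(as.character(spss@sequences), scheme@k, scheme@m,
                              scheme@seed)
    unamb <- res$nSuperKmers - res$nAmbiguousSuperKmers
    res$typeFractions <- if (unamb > 0) res$typeCounts / unamb else res$typeCounts
    if (!is.null(index)) {
        stopifnot(is(index, "LpMphf"))
        sp <- spaceReport(index)
        res$bitsTotal <- sp$total
        res$bitsPerKmer <- sp$bitsPerKmer
    }
    res
}

#' Measure the locality-preservation defect of an index
#'
#' Streams every SPSS string through the index and counts the positions i
#' (consecutive k-mer pairs within a string) whose codes are consecutive,
#' \code{f(x[i+1]) = f(x[i]) + 1}.  The locality defect is
#' \code{eps = 1 - |A| / n} where |A| is that count.  On a low-ambiguity
#' single-string SPSS eps concentrates around the minimizer density
#' \code{2/(w+1)}; string boundaries add alpha and ambiguous minimizers
#' add (at most) xi.
#'
#' @param index an [LpMphf-class] built over \code{spss}.
#' @param spss the [Spss-class] the index was built from.
#' @return A list with \code{n}, \code{nConsecutive} (|A|), and
#'   \code{epsilon}.
#' @export
measureEpsilon <- function(index, spss) {
    stopifnot(is(index, "LpMphf"), is(spss, "Spss"))
    cpp_measure_epsilon(index@bytes, as.character(spss@sequences))
}
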