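#' Build a minimal perfect hash function
#'
#' Constructs a bijection from the given distinct keys onto the codes
#' \code{0..n-1}, using multi-level collision-cascading bitmaps: at each
#' level every pending key hashes into a bitmap of \code{gamma} bits per
#' key; keys that land alone are assigned the rank of their bit, colliding
#' keys cascade to the next level, and a small remainder is stored in an
#' explicit table so construction always terminates.
#'
#' @param keys character vector of distinct keys.
#' @param seed non-negative integer master seed (per-level seeds are derived
#'   from it deterministically).
#' @param gamma bits per key allocated at each level (default 2; larger is
#'   faster to build and query but bigger).
#' @return An [Mphf-class].
#' @examples
#' f <- mphfBuild(c("A", "C", "G", "T"), seed = 1)
#' sort(mphfEval(f, c("A", "C", "G", "T"))) # 0 1 2 3
#' @export
mphfBuild <- function(keys, seed = 1, gamma = 2) {
    keys <- as.character(keys)
    if (length(keys) == 0L) stop("key set must be nonempty")
    if (anyDuplicated(keys))
        stop("duplicate key in MPHF input: \"", keys[anyDuplicated(keys)], "\"")
    new("Mphf", bytes = cpp_mphf_build(keys, as.numeric(seed), gamma),
        n = length(keys), seed = as.numeric(seed))
}

#' Evaluate a minimal perfect hash function
#'
#' @param f an [Mphf-class].
#' @param keys character vector of keys.
#' @return Numeric vector of codes in \code{0..n-1}.  Keys outside the
#'   construction set receive an arbitrary (deterministic) in-range value:
#'   an MPHF stores no membership information.
#' @export
mphfEval <- function(f, keys) {
    stopifnot(is(f, "Mphf"))
    cpp_mphf_eval(f@bytes, as.character(keys))
}

#' Serialize / deserialize an MPHF
#'
#' The byte format is the little-endian stream also embedded in index files:
#' key count, seed, gamma, the per-level bitmaps and the remainder table,
#' each length-prefixed.
#'
#' @param f an [Mphf-class].
#' @return \code{mphfSerialize}: a raw vector; \code{mphfDeserialize}: an
#'   [Mphf-class] answering identically to the original.
#' @export
mphfSerialize <- function(f) {
    stopifnot(is(f, "Mphf"))
    f@bytes
}

#' @param bytes a raw vector produced by \code{mphfSerialize}.
#' @rdname mphfSerialize
#' @export
mphfDeserialize <- function(bytes) {
    info <- cpp_mphf_info(bytes) # validates the stream
    new("Mphf", bytes = bytes, n = info$n, seed = NA_real_)
}

setMethod("show", "Mphf", function(object) {
    info <- cpp_mphf_info(object@bytes)
    cat("Mphf:", info$n, "keys,", info$nLevels, "level(s),",
        info$nRemainder, "in remainder table,",
        format(info$bitsPerKey, digits = 3), "bits/key\n")
})

#' @rdname spaceReport
#' @export
setMethod("spaceReport", "Mphf", function(x) cpp_mphf_info(x@bytes))
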