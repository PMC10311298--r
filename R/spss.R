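#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
NULL

.spssFrom <- function(seqs, k, validate = TRUE) {
    seqs <- toupper(as.character(seqs))
    if (validate) {
        res <- cpp_spss_validate(seqs, as.integer(k))
        if (!isTRUE(res$ok)) stop("SPSS validation failed: ", res$message)
        n <- res$n
    } else {
        n <- sum(nchar(seqs) - k + 1)
    }
    dss <- DNAStringSet(seqs)
    names(dss) <- names(seqs)
    new("Spss", sequences = dss, k = as.integer(k), n = as.numeric(n))
}

#' Read and validate an SPSS from a FASTA file
#'
#' Reads a (optionally gzipped) multi-record FASTA file and validates the
#' spectrum-preserving string set invariants for the given k: every string
#' has length >= k, contains only A,C,G,T (lowercase input is uppercased),
#' and every k-mer occurs exactly once across all records.  The first
#' duplicated k-mer, if any, is reported with both of its locations.
#'
#' @param path FASTA file path (gzip transparent).
#' @param k the k-mer length to validate for.
#' @param splitNonACGT if \code{TRUE}, records are split at runs of
#'   non-ACGT symbols (pieces shorter than k are dropped) before
#'   validation instead of rejecting such symbols.
#' @return An [Spss-class].
#' @seealso [writeSpss()], [syntheticSpss()]
#' @export
readSpss <- function(path, k, splitNonACGT = FALSE) {
    dss <- readDNAStringSet(path, format = "fasta")
    if (length(dss) == 0L) stop("no records in FASTA file: ", path)
    seqs <- toupper(as.character(dss))
    if (splitNonACGT) {
        ids <- names(seqs)
        pieces <- strsplit(seqs, "[^ACGT]+")
        seqs <- unlist(lapply(seq_along(pieces), function(i) {
            p <- pieces[[i]][nchar(pieces[[i]]) >= k]
            if (length(p)) names(p) <- paste0(ids[i], ".", seq_along(p))
            p
        }))
        if (length(seqs) == 0L)
            stop("no ACGT runs of length >= k after splitting")
    }
    .spssFrom(seqs, k)
}

#' Write an SPSS to a FASTA file
#'
#' Records are written in order with their identifiers and 80-column line
#' wrapping; \code{readSpss(writeSpss(x))} reproduces the strings in order.
#'
#' @param x an [Spss-class].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeSpss <- function(x, path) {
    stopifnot(is(x, "Spss"))
    seqs <- x@sequences
    if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
    writeXStringSet(seqs, filepath = path, width = 80L)
    invisible(path)
}

#' Generate a synthetic SPSS
#'
#' Draws random DNA strings with independent uniform bases under a global
#' distinct-k-mer constraint: each string grows base by base, candidate
#' bases are tried in random order, and a base whose newly completed k-mer
#' was already placed is rejected (the string is re-drawn in the vanishingly
#' rare event that all four candidates are taken).  The result is a valid
#' SPSS with exactly \code{nKmers} k-mers split into \code{nStrings} strings
#' of near-equal k-mer counts, hence fragmentation
#' \code{alpha = (nStrings - 1) / nKmers}.  Deterministic for a fixed seed.
#'
#' @param nKmers total number of k-mers to generate.
#' @param k k-mer length.
#' @param nStrings number of strings (default 1).
#' @param seed non-negative integer seed.
#' @return An [Spss-class].
#' @examples
#' s <- syntheticSpss(1000, k = 31, nStrings = 5, seed = 42)
#' nKmers(s) # 1000
#' @export
syntheticSpss <- function(nKmers, k, nStrings = 1, seed = 1) {
    if (2 * k < 62 && nKmers > 4^k / 20)
        warning("k-mer space 4^", k, " is not much larger than nKmers = ",
                nKmers, "; generation may be slow or fail", call. = FALSE)
    seqs <- cpp_spss_synthetic(as.numeric(nKmers), as.integer(k),
                               as.numeric(nStrings), as.numeric(seed))
    names(seqs) <- paste0("synth", seq_along(seqs))
    # generated under the constraint; re-validation is cheap insurance
    .spssFrom(seqs, k)
}

#' Validate SPSS invariants of raw strings
#'
#' @param strings character vector of DNA strings.
#' @param k k-mer length.
#' @return \code{TRUE} invisibly, or an error describing the first
#'   violation (short string, non-ACGT symbol, or duplicate k-mer with both
#'   of its locations).
#' @export
validateSpss <- function(strings, k) {
    res <- cpp_spss_validate(toupper(as.character(strings)), as.integer(k))
    if (!isTRUE(res$ok)) stop("SPSS validation failed: ", res$message)
    invisible(TRUE)
}

#' Extract all k-mers of sequences in order
#'
#' @param x character vector or [Spss-class].
#' @param k k-mer length (defaults to the Spss's k).
#' @return Character vector of all k-mers, string by string, left to right.
#' @export
extractKmers <- function(x, k = NULL) {
    if (is(x, "Spss")) {
        if (is.null(k)) k <- x@k
        x <- as.character(x@sequences)
    }
    if (is.null(k)) stop("k must be given for character input")
    cpp_extract_kmers(as.character(x), as.integer(k))
}

#' @rdname nKmers
#' @export
setMethod("nKmers", "Spss", function(x) x@n)

#' @rdname kmerLength
#' @export
setMethod("kmerLength", "Spss", function(x) x@k)

#' Coerce an Spss to the underlying character vector
#'
#' @param x an [Spss-class].
#' @param ... ignored.
#' @return Character vector of the strings, named by record identifier.
#' @export
setMethod("as.character", "Spss", function(x, ...) as.character(x@sequences))

setMethod("show", "Spss", function(object) {
    widths <- BiocGenerics::width(object@sequences)
    cat("Spss:", length(object@sequences), "string(s),", format(object@n, big.mark = ","),
        "distinct", paste0(object@k, "-mers;"),
        "lengths", min(widths), "..", max(widths), "\n")
})

#' @rdname fragmentation
#' @export
setGeneric("fragmentation", function(x) standardGeneric("fragmentation"))

#' Fragmentation factor of an SPSS
#'
#' \code{alpha = (|S| - 1) / n}: the inherent fraction of consecutive-code
#' losses due to string boundaries.  It is 0 for a single string and
#' approaches \code{1 - 1/n} when every string holds a single k-mer.
#'
#' @param x an [Spss-class].
#' @return The fragmentation factor in \code{[0, 1)}.
#' @examples
#' fragmentation(syntheticSpss(100, 31, nStrings = 5, seed = 1)) # 0.04
#' @name fragmentation
#' @export
setMethod("fragmentation", "Spss", function(x) {
    (length(x@sequences) - 1) / x@n
})
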