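writeFasta <- function(records, path) {
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

test_that("reading validates the SPSS invariants", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeFasta(list(r1 = "ACGTACGTACG"), path)
  s <- readSpss(path, k = 11)
  expect_equal(nKmers(s), 1)
  expect_equal(length(s@sequences), 1L)

  writeFasta(list(a = "ACGTA", b = "CGTAC"), path)
  s <- readSpss(path, k = 5)
  expect_equal(nKmers(s), 2)

  # duplicate k-mer across records is named with both locations
  writeFasta(list(a = "ACGTAC", b = "TACGTA"), path)
  expect_error(readSpss(path, k = 5), "duplicate k-mer 'ACGTA'")
  # string shorter than k
  writeFasta(list(a = "ACGT"), path)
  expect_error(readSpss(path, k = 5), "shorter than k")
  # non-ACGT symbol rejected unless splitting is requested
  writeFasta(list(a = "ACGTTNACGTA"), path)
  expect_error(readSpss(path, k = 5), "non-ACGT")
  s <- readSpss(path, k = 5, splitNonACGT = TRUE)
  expect_equal(as.vector(nKmers(s)), 2)
  # lowercase input is accepted and uppercased
  writeFasta(list(a = "acgtacgtacg"), path)
  expect_equal(as.character(readSpss(path, k = 11)@sequences)[[1]],
               "ACGTACGTACG")
})

test_that("write/read round-trips strings, order and identifiers", {
  s <- syntheticSpss(300, 31, nStrings = 3, seed = 41)
  path <- withr::local_tempfile(fileext = ".fa")
  writeSpss(s, path)
  s2 <- readSpss(path, k = 31)
  expect_identical(as.character(s2@sequences), as.character(s@sequences))
  expect_identical(names(s2@sequences), names(s@sequences))
  # 80-column wrapping
  expect_true(all(nchar(readLines(path)) <= 80))
})

test_that("gzipped FASTA is read transparently", {
  s <- syntheticSpss(100, 31, seed = 43)
  plain <- withr::local_tempfile(fileext = ".fa")
  writeSpss(s, plain)
  gz <- withr::local_tempfile(fileext = ".fa.gz")
  con <- gzfile(gz, "wb")
  writeLines(readLines(plain), con)
  close(con)
  expect_identical(as.character(readSpss(gz, 31)@sequences),
                   as.character(s@sequences))
})

test_that("the synthetic generator is deterministic and hits its targets", {
  one <- syntheticSpss(1, 31, seed = 51)
  expect_equal(nchar(as.character(one@sequences)), 31L)
  a <- syntheticSpss(1e4, 31, nStrings = 5, seed = 7)
  b <- syntheticSpss(1e4, 31, nStrings = 5, seed = 7)
  expect_identical(as.character(a@sequences), as.character(b@sequences))
  expect_false(identical(as.character(a@sequences),
                         as.character(syntheticSpss(1e4, 31, nStrings = 5, seed = 8)@sequences)))
  expect_equal(nKmers(a), 1e4)
  expect_equal(fragmentation(a), 4 / 1e4)
})

test_that("generated sets satisfy the SPSS invariants across parameterizations", {
  set.seed(61)
  cases <- data.frame(n = sample(10:2000, 20), k = sample(c(15L, 21L, 31L, 63L), 20, TRUE),
                      s = sample(1:5, 20, TRUE))
  for (i in seq_len(nrow(cases))) {
    n <- max(cases$n[i], cases$s[i])
    sp <- syntheticSpss(n, cases$k[i], cases$s[i], seed = i)
    expect_equal(nKmers(sp), n)
    expect_true(validateSpss(as.character(sp@sequences), cases$k[i]))
    expect_equal(length(sp@sequences), cases$s[i])
  }
})

test_that("infeasible or borderline generator parameters are rejected or flagged", {
  expect_error(suppressWarnings(syntheticSpss(1000, 3, seed = 1)), "infeasible")
  expect_warning(syntheticSpss(100, 4, nStrings = 10, seed = 1), "not much larger")
  expect_error(syntheticSpss(2, 31, nStrings = 5, seed = 1), "nKmers >= nStrings")
})
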