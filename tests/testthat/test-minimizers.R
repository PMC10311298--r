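test_that("minimizerScheme validates its parameters and warns in the low-m regime", {
  sc <- minimizerScheme(31, 21, seed = 3)
  expect_equal(windowCount(sc), 11L)
  expect_error(minimizerScheme(5, 9), "m must not exceed k")
  expect_error(minimizerScheme(0, 0))
  # m at or below (3+eps)*log4(w+1) only warns, it does not error
  expect_warning(minimizerScheme(31, 4, seed = 1), "density regime")
  expect_silent(minimizerScheme(31, 15, seed = 1))
})

test_that("minimizer of a k-mer: degenerate and all-tie cases", {
  # m = k: the k-mer itself is the only candidate
  sc <- minimizerScheme(8, 8, seed = 5)
  res <- minimizerOfKmer("ACGTACGT", sc)
  expect_equal(res$mmer, "ACGTACGT")
  expect_equal(res$pos, 1L)
  # all m-mers identical: leftmost wins
  sc <- minimizerScheme(8, 4, seed = 5)
  res <- minimizerOfKmer("AAAAAAAA", sc)
  expect_equal(res$mmer, "AAAA")
  expect_equal(res$pos, 1L)
})

test_that("minimizer of a k-mer matches brute-force enumeration on random input", {
  sc <- minimizerScheme(31, 21, seed = 11)
  for (i in 1:100) {
    kmer <- randomDna(31, seed = 1000 + i)
    got <- minimizerOfKmer(kmer, sc)
    want <- naiveMinimizer(kmer, sc)
    expect_equal(got$mmer, want$mmer)
    expect_equal(got$pos, want$pos)
    expect_equal(got$hash, want$hash)
  }
})

test_that("minimizer input errors name the offending position", {
  sc <- minimizerScheme(8, 4, seed = 1)
  expect_error(minimizerOfKmer("ACGT", sc), "length 4")
  expect_error(minimizerOfKmer("ACGTNCGT", sc), "position 5")
})

test_that("streaming minimizers equal per-k-mer recomputation", {
  sc <- minimizerScheme(31, 15, seed = 21)
  s <- randomDna(200, seed = 77)
  hits <- streamingMinimizers(s, sc)
  expect_equal(nrow(hits), 170L)
  for (i in seq_len(nrow(hits))) {
    want <- naiveMinimizer(substr(s, i, i + 30), sc)
    expect_equal(hits$mmer[i], want$mmer)
    expect_equal(hits$pos[i], want$pos)
  }
  # |sequence| = k: single hit identical to minimizerOfKmer
  one <- streamingMinimizers(substr(s, 1, 31), sc)
  expect_equal(nrow(one), 1L)
  expect_equal(one$mmer, minimizerOfKmer(substr(s, 1, 31), sc)$mmer)
  # constant sequence: every hit is the leftmost all-A m-mer
  aaa <- streamingMinimizers(strrep("A", 200), sc)
  expect_true(all(aaa$mmer == strrep("A", 15)))
  expect_true(all(aaa$pos == 1L))
  expect_error(streamingMinimizers("ACGT", sc), "shorter than k")
})

test_that("super-k-mer decomposition partitions the k-mers and obeys the position identities", {
  sc <- minimizerScheme(31, 15, seed = 9)
  w <- windowCount(sc)
  s <- randomDna(300, seed = 5)
  g <- superKmers(s, sc)
  nk <- nchar(s) - 31 + 1
  expect_equal(sum(g$size), nk)                      # partition
  expect_equal(g$size, g$length - 31L + 1L)
  expect_equal(g$pLast, g$pFirst - g$size + 1L)      # p_{g,i} = p_{g,1} - i + 1
  expect_true(all(g$size <= g$pFirst & g$pFirst <= w))
  # k-mer runs agree with the naive grouping oracle
  want <- naiveSuperKmers(s, sc)
  expect_equal(g$size, want$size)
  expect_equal(g$pFirst, want$pFirst)
  expect_equal(as.character(g$minimizer), want$minimizer)
  # per-k-mer minimizer positions within each super-k-mer decrease by one
  hits <- streamingMinimizers(s, sc)
  for (r in seq_len(nrow(g))) {
    idx <- (g$start[r] + 1):(g$start[r] + g$size[r])
    expect_equal(hits$pos[idx], g$pFirst[r] - seq_along(idx) + 1L)
  }
  # single k-mer sequence: one super-k-mer of size 1
  g1 <- superKmers(substr(s, 1, 31), sc)
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$size, 1L)
  expect_equal(g1$pFirst, g1$pLast)
})

test_that("a length-16 super-k-mer at k=13 spans exactly 4 k-mers", {
  sc <- minimizerScheme(13, 7, seed = 1)
  # search deterministic random strings for a super-k-mer of length 16
  found <- NULL
  for (i in 1:200) {
    g <- superKmers(randomDna(60, seed = i), sc)
    hit <- which(g$length == 16L)
    if (length(hit)) { found <- g[hit[1], ]; break }
  }
  expect_false(is.null(found))
  expect_equal(found$size, 16L - 13L + 1L) # = 4
})

test_that("rank within a super-k-mer follows pFirst - p + 1 with out-of-range NA", {
  expect_equal(rankInSuperKmer(5, pFirst = 5, size = 3), 1L) # first k-mer
  expect_equal(rankInSuperKmer(3, pFirst = 5, size = 3), 3L) # last k-mer
  got <- rankInSuperKmer(1:7, pFirst = 5, size = 3)
  expect_equal(got, c(NA, NA, 3L, 2L, 1L, NA, NA))
})

test_that("FL classification covers the worked quadruples and partitions all pairs", {
  expect_equal(as.character(classifySuperKmer(c(7, 5, 7, 4), c(1, 1, 3, 2), w = 7)),
               c("left-right-max", "left-max", "right-max", "non-max"))
  expect_equal(as.character(classifySuperKmer(1, 1, w = 1)), "left-right-max")
  # every admissible (pFirst, pLast) pair gets exactly one type
  grid <- expand.grid(pFirst = 1:7, pLast = 1:7)
  grid <- grid[grid$pLast <= grid$pFirst, ]
  types <- classifySuperKmer(grid$pFirst, grid$pLast, w = 7)
  expect_false(anyNA(types))
  expect_equal(sum(grid$pFirst == 7 & grid$pLast == 1), sum(types == "left-right-max"))
  expect_error(classifySuperKmer(3, 5, w = 7), "pLast <= pFirst")
})

test_that("empirical super-k-mer density matches 2/(w+1) on long random input", {
  sc <- minimizerScheme(31, 21, seed = 13) # w = 11
  s <- as.character(syntheticSpss(1e5, 31, seed = 13)@sequences)
  g <- superKmers(s, sc)
  d <- expectedDensity(windowCount(sc))
  sigma <- sqrt(d * (1 - d) / 1e5)
  expect_lt(abs(nrow(g) / 1e5 - d), 4 * sigma)
})
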