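test_that("bitvector rank matches naive popcount on fixed and random inputs", {
  expect_equal(bvRank1(rankBitVector(integer(0)), 0), 0)
  expect_equal(bvRank1(rankBitVector(rep(1L, 100)), 57), 57)
  set.seed(42)
  bits <- sample(0:1, 10000, replace = TRUE)
  bv <- rankBitVector(bits)
  grid <- sort(sample(0:10000, 200))
  expect_equal(bvRank1(bv, grid), cumsum(c(0, bits))[grid + 1])
  # rank is monotone with unit increments
  all_r <- bvRank1(bv, 0:10000)
  expect_true(all(diff(all_r) %in% 0:1))
  expect_equal(all_r[10001], sum(bits))
  expect_error(bvRank1(bv, 10001), "out of range")
})

test_that("Elias-Fano round-trips exactly, including duplicates", {
  expect_equal(efAccess(eliasFano(0), 1), 0)
  v <- c(0, 0, 0, 5, 5, 9)
  expect_equal(efAccess(eliasFano(v), 1:6), v)
  set.seed(7)
  v <- sort(sample(0:1e6, 1000, replace = TRUE))
  ef <- eliasFano(v)
  expect_equal(efAccess(ef, 1:1000), v)
  # compression: about n*(2 + log2(universe/n)) bits plus fixed overhead
  bits <- spaceReport(ef)$bitsTotal
  expect_lt(bits, 1000 * (2 + ceiling(log2(1e6 / 1000))) + 2500)
  expect_error(eliasFano(c(3, 2)), "non-decreasing")
  expect_error(eliasFano(c(-1, 2)), "non-negative")
})

test_that("wavelet tree access and per-symbol rank agree with naive scans", {
  wt <- waveletTree4(2L)
  expect_equal(wtRank(wt, 2, 1), 1)
  expect_equal(wtRank(wt, 0, 1), 0)
  wt <- waveletTree4(rep(0:3, 2))
  expect_equal(wtRank(wt, 3, 8), 2)
  set.seed(11)
  syms <- sample(0:3, 5000, replace = TRUE)
  wt <- waveletTree4(syms)
  probes <- sample(1:5000, 100)
  expect_equal(wtAccess(wt, probes), syms[probes])
  for (t in 0:3)
    expect_equal(wtRank(wt, t, probes), cumsum(syms == t)[probes])
  # ranks over all four symbols partition every prefix
  expect_equal(Reduce(`+`, lapply(0:3, function(t) wtRank(wt, t, probes))),
               as.numeric(probes))
  expect_error(waveletTree4(c(0L, 4L)), "out of")
})

test_that("wavelet tree stays within 2.5 bits per symbol", {
  syms <- rep(0:3, length.out = 4096)
  info <- spaceReport(waveletTree4(syms))
  expect_equal(info$bitsPayload, 2 * 4096)
  # rank directories must cost at most 50% of the 2-bit payload
  expect_lte(info$bitsTotal - 512, 2.5 * 4096) # 512 = fixed header words
})
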