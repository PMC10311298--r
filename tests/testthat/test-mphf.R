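randomKeys <- function(n, len, seed) {
  set.seed(seed)
  unique(vapply(seq_len(n * 2), function(i)
    paste(sample(c(LETTERS, letters, 0:9), len, replace = TRUE), collapse = ""),
    character(1)))[seq_len(n)]
}

test_that("MPHF evaluation is a bijection onto 0..n-1 over the key set", {
  f <- mphfBuild("onlykey", seed = 3)
  expect_equal(mphfEval(f, "onlykey"), 0)
  keys <- randomKeys(1000, 21, seed = 4)
  f <- mphfBuild(keys, seed = 4)
  expect_equal(sort(mphfEval(f, keys)), as.numeric(0:999))
  # determinism: same seed, same function
  f2 <- mphfBuild(keys, seed = 4)
  expect_identical(mphfEval(f2, keys), mphfEval(f, keys))
  # small alphabet set
  f <- mphfBuild(c("A", "C", "G", "T"), seed = 1)
  expect_equal(sort(mphfEval(f, c("A", "C", "G", "T"))), as.numeric(0:3))
})

test_that("alien keys evaluate to some in-range value and duplicates are rejected", {
  keys <- randomKeys(500, 12, seed = 9)
  f <- mphfBuild(keys, seed = 9)
  aliens <- randomKeys(200, 13, seed = 10)
  vals <- mphfEval(f, aliens)
  expect_true(all(vals >= 0 & vals <= 499))
  expect_error(mphfBuild(c("a", "b", "a"), seed = 1), "duplicate key")
})

test_that("MPHF bijectivity holds across many random key-set sizes", {
  set.seed(100)
  sizes <- c(1, 2, 3, sample(4:2000, 27))
  for (i in seq_along(sizes)) {
    n <- sizes[i]
    keys <- randomKeys(n, 8, seed = 200 + i)
    f <- mphfBuild(keys, seed = i)
    expect_equal(sort(mphfEval(f, keys)), as.numeric(0:(n - 1)))
  }
})

test_that("MPHF space stays within the sanity bound and survives serialization", {
  keys <- randomKeys(2000, 21, seed = 5)
  f <- mphfBuild(keys, seed = 5)
  expect_lte(spaceReport(f)$bitsPerKey, 8)
  f2 <- mphfDeserialize(mphfSerialize(f))
  expect_identical(mphfEval(f2, keys), mphfEval(f, keys))
})
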