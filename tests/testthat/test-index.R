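bothLayouts <- c("partitioned", "unpartitioned")

test_that("a single-k-mer SPSS yields the degenerate one-slot index", {
  s <- syntheticSpss(1, 31, seed = 2)
  sc <- minimizerScheme(31, 15, seed = 2)
  for (lay in bothLayouts) {
    ix <- lpMphf(s, sc, layout = lay)
    expect_equal(nKmers(ix), 1)
    expect_equal(ix@nMinimizers, 1)
    expect_equal(lookupKmers(ix, as.character(s@sequences)), 0)
  }
  ixu <- lpMphf(s, sc, layout = "unpartitioned")
  comp <- indexComponents(ixu)
  expect_equal(comp$L, c(0, 1))
  expect_true(comp$P >= 1 && comp$P <= windowCount(sc))
  # partitioned: the slot type matches the FL classification of the super-k-mer
  ixp <- lpMphf(s, sc)
  g <- superKmers(s, sc)
  expect_equal(indexComponents(ixp)$types,
               as.integer(g$flType) - 1L)
})

test_that("slot sizes and fallback keys account for every k-mer", {
  s <- syntheticSpss(470, 31, seed = 6) # one 500-symbol string
  sc <- minimizerScheme(31, 15, seed = 6)
  ixu <- lpMphf(s, sc, layout = "unpartitioned")
  comp <- indexComponents(ixu)
  info <- indexInfo(ixu)
  expect_equal(comp$L[length(comp$L)] + info$nFallback, 470)
  expect_true(all(diff(comp$L) >= 0))
  sizes <- diff(comp$L)
  w <- windowCount(sc)
  ok <- sizes > 0 # unambiguous slots
  expect_true(all(sizes[ok] <= w))
  expect_true(all(sizes[ok] <= comp$P[ok] & comp$P[ok] <= w))
  # partitioned totals conserve the k-mer count
  ixp <- lpMphf(s, sc)
  infop <- indexInfo(ixp)
  expect_equal(sum(infop$kmerTotals) + infop$nFallback, 470)
})

test_that("lookups over the full spectrum are exact permutations in both layouts", {
  s <- syntheticSpss(4000, 31, nStrings = 3, seed = 8)
  sc <- minimizerScheme(31, 15, seed = 8)
  for (lay in bothLayouts) {
    ix <- lpMphf(s, sc, layout = lay)
    codes <- unlist(lookupStreaming(ix, s))
    expect_equal(sort(codes), as.numeric(0:3999))
    # random-access path agrees elementwise with streaming
    expect_identical(lookupKmers(ix, extractKmers(s)), codes)
  }
})

test_that("codes are consecutive inside every unambiguous super-k-mer", {
  s <- syntheticSpss(3000, 31, nStrings = 2, seed = 14)
  sc <- minimizerScheme(31, 15, seed = 14)
  g <- superKmers(s, sc)
  amb <- names(which(table(g$minimizer) > 1))
  for (lay in bothLayouts) {
    ix <- lpMphf(s, sc, layout = lay)
    codes <- lookupStreaming(ix, s)
    if (!is.list(codes)) codes <- list(codes)
    for (r in which(!(g$minimizer %in% amb))) {
      run <- codes[[g$stringId[r]]][(g$start[r] + 1):(g$start[r] + g$size[r])]
      if (length(run) > 1) expect_equal(diff(run), rep(1, length(run) - 1))
    }
  }
})

test_that("an ambiguous minimizer gets the size-0 sentinel and its k-mers the tail codes", {
  # small m on a long string makes repeated minimizer values overwhelmingly likely
  sc <- suppressWarnings(minimizerScheme(15, 4, seed = 3)) # deliberately low m
  s <- NULL
  for (seed in 1:50) {
    cand <- syntheticSpss(400, 15, seed = seed)
    g <- superKmers(cand, sc)
    if (anyDuplicated(g$minimizer)) { s <- cand; break }
  }
  expect_false(is.null(s))
  g <- superKmers(s, sc)
  amb <- names(which(table(g$minimizer) > 1))[1]
  st <- measureScheme(s, sc)
  expect_gt(st$nAmbiguousMinimizers, 0)
  expect_equal(st$xi, st$nAmbiguousKmers / 400)

  ixu <- suppressWarnings(lpMphf(s, sc, layout = "unpartitioned"))
  ixp <- suppressWarnings(lpMphf(s, sc, layout = "partitioned"))
  info <- indexInfo(ixu)
  expect_equal(info$nFallback, st$nAmbiguousKmers)
  # the ambiguous slot has recorded size 0 in L
  sizes <- diff(indexComponents(ixu)$L)
  expect_equal(sum(sizes == 0), st$nAmbiguousMinimizers)
  # ambiguous slots are typed right-max with a size-0 entry in Lr
  compp <- indexComponents(ixp)
  expect_equal(sum(diff(compp$Lr) == 0), st$nAmbiguousMinimizers)
  # k-mers of the ambiguous minimizer land in the fallback tail, in both layouts
  ambRows <- g[g$minimizer == amb, ]
  ambKmers <- unlist(lapply(seq_len(nrow(ambRows)), function(i) {
    str <- as.character(s@sequences)[ambRows$stringId[i]]
    substrKmers(substr(str, ambRows$start[i] + 1,
                       ambRows$start[i] + ambRows$length[i]), 15)
  }))
  for (ix in list(ixu, ixp)) {
    expect_true(all(lookupKmers(ix, ambKmers) >= indexInfo(ix)$nUnambiguous))
    codes <- unlist(lookupStreaming(ix, s))
    expect_equal(sort(codes), as.numeric(0:399)) # still minimal perfect
  }
  # identical fallback key sets across layouts: same tail codes for same k-mers
  expect_identical(lookupKmers(ixu, ambKmers) >= info$nUnambiguous,
                   lookupKmers(ixp, ambKmers) >= indexInfo(ixp)$nUnambiguous)
})

test_that("slot types stored in the wavelet tree match recomputed classifications", {
  s <- syntheticSpss(2000, 31, seed = 17)
  sc <- minimizerScheme(31, 15, seed = 17)
  ix <- lpMphf(s, sc)
  g <- superKmers(s, sc)
  # no ambiguity expected at this scale/m; map minimizer -> type code
  expect_equal(max(table(g$minimizer)), 1L)
  types <- indexComponents(ix)$types
  expect_equal(length(types), nrow(g))
  # fm permutes the slots, so compare as multisets of type codes
  expect_equal(as.vector(table(factor(types, 0:3))),
               as.vector(table(factor(as.integer(g$flType) - 1L, 0:3))))
  expect_equal(as.vector(indexInfo(ix)$slotCounts),
               as.vector(table(g$flType)))
})

test_that("streaming and random lookups coincide on alien query sequences", {
  s <- syntheticSpss(2000, 31, seed = 19)
  sc <- minimizerScheme(31, 15, seed = 19)
  q <- randomDna(500, seed = 999) # almost surely not in the index
  for (lay in bothLayouts) {
    ix <- lpMphf(s, sc, layout = lay)
    stream <- lookupStreaming(ix, q)
    random <- lookupKmers(ix, substrKmers(q, 31))
    expect_identical(stream, random)
    expect_true(all(stream >= 0 & stream < 2000))
    # strict mode: identical pattern of detected non-members on both paths
    expect_identical(lookupStreaming(ix, q, strict = TRUE),
                     lookupKmers(ix, substrKmers(q, 31), strict = TRUE))
    # indexed k-mers are never flagged in strict mode
    own <- lookupKmers(ix, extractKmers(s)[1:100], strict = TRUE)
    expect_false(anyNA(own))
  }
})

test_that("serialization round-trips and corrupt files are rejected", {
  s <- syntheticSpss(800, 31, nStrings = 2, seed = 23)
  sc <- minimizerScheme(31, 15, seed = 23)
  ix <- lpMphf(s, sc)
  path <- withr::local_tempfile(fileext = ".lpmh")
  saveIndex(ix, path)
  ix2 <- loadIndex(path)
  expect_identical(ix2@bytes, ix@bytes)
  expect_identical(lookupKmers(ix2, extractKmers(s)), lookupKmers(ix, extractKmers(s)))
  bytes <- readBin(path, "raw", n = file.size(path))
  # truncation
  writeBin(bytes[1:64], path)
  expect_error(loadIndex(path), "truncated")
  # bad magic
  writeBin(c(as.raw(0:3), bytes[-(1:4)]), path)
  expect_error(loadIndex(path), "magic")
  # version mismatch (version field is the little-endian u16 at offsets 5:6)
  bad <- bytes
  bad[5] <- as.raw(99)
  writeBin(bad, path)
  expect_error(loadIndex(path), "version")
})

test_that("two builds from identical inputs are byte-identical", {
  s <- syntheticSpss(600, 31, seed = 29)
  sc <- minimizerScheme(31, 15, seed = 29)
  a <- lpMphf(s, sc)
  b <- lpMphf(s, sc)
  expect_identical(a@bytes, b@bytes)
})
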