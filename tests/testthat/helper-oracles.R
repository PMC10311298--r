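# Shared helpers: naive reference implementations used as oracles, and
# small deterministic fixtures built in code.

# random DNA string (not necessarily distinct k-mers; for oracle tests only)
randomDna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substrKmers <- function(s, k) {
  n <- nchar(s) - k + 1
  vapply(seq_len(n), function(i) substr(s, i, i + k - 1), character(1))
}

# brute-force minimizer: enumerate all m-mers, order by (hash hex, position)
naiveMinimizer <- function(kmer, scheme) {
  k <- kmerLength(scheme); m <- minimizerLength(scheme)
  mm <- substrKmers(kmer, m)
  hx <- mmerHash(mm, scheme)
  best <- which(hx == min(hx))[1] # fixed-width hex: lexicographic == numeric
  list(mmer = mm[best], pos = best, hash = hx[best])
}

# naive super-k-mer grouping from per-k-mer minimizer occurrences
naiveSuperKmers <- function(s, scheme) {
  hits <- streamingMinimizers(s, scheme)
  runs <- rle(hits$absPos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  data.frame(kmerStart = starts, size = runs$lengths,
             pFirst = runs$values - starts + 2, # 0-based abs - 0-based kmer + 1
             minimizer = hits$mmer[starts])
}

# fixture cache so expensive builds are shared across test files
.fixtureEnv <- new.env(parent = emptyenv())
cachedFixture <- function(key, maker) {
  if (!exists(key, envir = .fixtureEnv)) assign(key, maker(), envir = .fixtureEnv)
  get(key, envir = .fixtureEnv)
}
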