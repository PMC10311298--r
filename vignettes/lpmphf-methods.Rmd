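---
title: "Locality-preserving minimal perfect hashing of k-mers: methods and design"
author: "lpmphf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locality-preserving minimal perfect hashing of k-mers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpmphf)
```

## The problem

A minimal perfect hash function (MPHF) maps n distinct keys bijectively onto
the integers 0..n-1.  For arbitrary keys this costs at least log2(e) = 1.44
bits per key.  But the k-mers of a genomic sequence collection are not
arbitrary: consecutive k-mers overlap by k-1 symbols.  `lpmphf` exploits this
to build MPHFs for the distinct k-mers of a *spectrum-preserving string set*
(SPSS — a set of strings, e.g. unitigs of a compacted de Bruijn graph, in
which every k-mer occurs exactly once) that (i) take well under 1.44 bits per
k-mer for large k and (ii) are *locality-preserving*: consecutive k-mers of a
string receive consecutive hash codes for most positions.  Locality matters
in practice because satellite arrays indexed by the hash code (abundances,
colors, unitig ids) then cluster similar values together, and because
streaming queries of consecutive k-mers become very cheap.

The locality defect is measured by epsilon: with A the set of positions i
such that k-mers x_i and x_{i+1} are consecutive in a string and
f(x_{i+1}) = f(x_i) + 1, the function is (1-eps)-locality-preserving when
eps >= 1 - |A|/n.  Two quantities bound what is achievable: the
*fragmentation factor* alpha = (|S|-1)/n (consecutive codes are impossible
across string boundaries) and the *ambiguous-minimizer fraction* xi
(defined below).

## The construction

**Random minimizers.** A scheme (k, m, h) selects, inside every k-mer, the
m-mer with smallest value under a seeded 64-bit random hash h, ties broken
leftmost; w = k - m + 1 is the number of candidate windows.  A
*super-k-mer* is a maximal run of consecutive k-mers selecting the same
minimizer occurrence.  If p1 is the (1-based) position of the minimizer in
the first k-mer of a super-k-mer g, the position in the i-th k-mer is
p1 - i + 1, so the rank of a k-mer inside g is recoverable from the
minimizer position alone: rank = p1 - p + 1 (the *implicit ranking*).  Two
consequences follow directly: the number of k-mers in g is at most p1,
which is at most w; and consecutive k-mers of g have ranks differing by 1,
which is what makes the final function locality-preserving inside every
super-k-mer.

**Unpartitioned layout.** Build an inner MPHF f_m over the |M| distinct
minimizers.  Store, in f_m order, the prefix sums L of super-k-mer sizes
(an Elias-Fano sequence over universe n) and the positions p1 in a
fixed-width bit-packed array P.  A lookup computes (mu, p) of the query
k-mer, i = f_m(mu), and returns L[i] + P[i] - p: prefix sum as the global
component, implicit rank as the local component.  Restricted to the indexed
spectrum this is a bijection onto 0..n-1 (0-based codes; the per-slot
arithmetic natively produces them and we keep the algorithm literal).

**Partitioned layout.** The inequality size <= p1 <= w means that a
super-k-mer of maximal size w necessarily has p1 = w, and one whose last
k-mer has the minimizer at position 1 has size = p1.  The first/last (FL)
rule classifies each super-k-mer by whether p1 = w ("left max") and whether
the last k-mer's position is 1 ("right max"), giving four types:
left-right-max (both), left-max, right-max, non-max.  Per type, redundant
storage is dropped:

* left-right-max: nothing stored — size = p1 = w are implied;
* left-max: only the size prefix sums Ll (p1 = size is implied);
* right-max: only the size prefix sums Lr (p1 = w is implied);
* non-max: size prefix sums Ln and explicit positions Pn.

The type of each slot is stored in a 4-symbol wavelet tree R (2 bits/symbol
payload) supporting access and per-symbol prefix rank in constant time; the
rank of a slot among its type addresses the per-type arrays.  The global
code is prefix + offset + p1 - p, where the per-type prefixes are the
cumulative k-mer totals of the preceding partitions in the fixed order
left-right-max, left-max, right-max, non-max.  These k-mer totals (e.g.
w times the number of left-right-max slots) — not super-k-mer counts — are
the only reading under which the formula is a bijection onto the codomain.

**Ambiguous minimizers.** When more than one super-k-mer shares a minimizer
value, a single stored (size, p1) cannot place its k-mers; such minimizers
are *ambiguous* and all their k-mers are routed to a *fallback MPHF*
occupying the tail of the codomain, [n - n_fallback, n).  Rather than an
explicit flag bit per minimizer, the slot keeps a size-0 sentinel (a
super-k-mer of size 0 is impossible): in the unpartitioned layout a zero
increment in L, in the partitioned layout the slot is typed right-max with
a zero increment in Lr, so the sentinel never perturbs any prefix sum.  The
fraction xi of k-mers with ambiguous minimizers decreases as m grows; on
random DNA at desk scale it is essentially zero, while repetitive genomes
show a few percent.  If every minimizer is ambiguous the index degrades
gracefully to fallback-only and remains minimal perfect.

**Streaming queries.** Because consecutive k-mers usually share a minimizer
occurrence, the streaming path slides the minimizer window along the query,
resolves the slot once per run, and emits the per-k-mer codes by the same
arithmetic as the random-access path — so its output is elementwise
identical, by construction, including on alien (non-indexed) k-mers.

## Closed-form expectations

For a random minimizer scheme with m above (3+eps) log4(w+1), the expected
super-k-mer density is 2/(w+1) (lower-order terms dropped), which is also
the expected locality defect of the index on a single-string SPSS up to
alpha and xi.  The FL-type probabilities follow from a discrete Markov
model of the minimizer position: with W = (1 - 1/w)/2,

* P(left-right-max) = W^2 + 1/w,
* P(left-max) = P(right-max) = W(1 - W),
* P(non-max) = W^2.

They sum to one, and the unpartitioned space bound

n * 2/(w+1) * (log2(4 (w+1)^2) + b + o(1))   bits,

with b > log2(e) the inner MPHF's bits/key, decreases as w grows.  All o(.)
terms are represented by one user-settable `overhead` constant, default
0.5, which matches the rank-directory overheads of the concrete structures;
exact asymptotics are out of scope.  The analogous bound for the
partitioned layout is not computed — the extra constant it would need is
not pinned down by the analysis here — and the partitioned layout is instead validated
empirically against the unpartitioned one (it is consistently smaller).

**Accuracy of the type probabilities.** The Markov model's product step
(treating the first-k-mer and last-k-mer events as independent) carries a
small O(1/w) bias.  Empirically, at w = 11 the measured fractions on large
random DNA are about (0.286, 0.260, 0.260, 0.195) against computed
(0.2975, 0.2479, 0.2479, 0.2066) — a deviation of ~0.01 that shrinks as w
grows and far exceeds binomial noise once more than ~10^5 super-k-mers are
measured.  The exact sub-identities *are* observed: the fractions sum to 1,
left and right fractions agree, and P(lr) - P(n) = 1/w.  The package's
statistical tests therefore check the closed form against measurement at a
scale (10^4 k-mers) where sampling noise dominates this model bias, and
check the exact identities at all scales.  The same pattern — measured
left-right-max below the computed value by about 0.01-0.02 at small w,
converging as w grows — appears when the fractions are measured on real
genomes.

## Concrete data structures and numerical choices

* **Hash h**: seeded 64-bit MurmurHash2 over the ASCII bytes of the
  uppercase m-mer.  The contract is determinism given (m-mer, seed); the
  byte encoding is fixed and recorded here because it is baked into the
  serialized format.  Hash universe 2^64 makes ties (resolved leftmost)
  astronomically rare but they are handled exactly.
* **Positions** are 1-based inside k-mers (p, p1 in 1..w), keeping the
  rank formulas literal; offsets of super-k-mers inside strings are 0-based
  half-open, the conventional slicing form.
* **Rank bitvector**: absolute 64-bit counters every 512 bits (Rank9
  flavour; 12.5% overhead).  The contract is exact rank; the block size
  only trades space for speed.
* **Elias-Fano**: low-bit width floor(log2(universe/n)); select-accelerated
  access via sampled positions of every 256th high bit.  Exactness, not
  speed, is the tested contract.
* **Wavelet tree**: two rank bitvector levels (high bit, then low bits
  grouped by high bit); 2 bits/symbol payload, <= 2.5 bits/symbol total.
* **Inner MPHF**: multi-level collision-cascading bitmaps (gamma = 2 bits
  per key per level, seeds derived from the master seed by splitmix64),
  with an explicit sorted remainder table after 48 levels guaranteeing
  termination; ~3.5-4 bits/key in practice.  The construction treats the
  inner MPHF as a pluggable contract — only determinism, bijectivity and
  in-range evaluation of alien keys are relied upon.
* **P is bit-packed fixed-width**, not Elias-Fano: positions are not
  monotone, so the prefix-sum trick does not apply directly; ceil(log2 w)
  bits per entry is within a fraction of a bit of entropy anyway.
  Ambiguous slots store the filler value w, which is never read.
* **Alien k-mers** may receive any in-range code (an MPHF is not a
  membership structure).  Out-of-range arithmetic, possible only for
  aliens, is folded back deterministically; an optional strict mode applies
  the rank-range check and reports NA where non-membership is detectable
  (false negatives impossible, false positives expected).
* **Determinism**: strings are processed in file order, slots in f_m
  order, all seeds derive from the one scheme seed; two builds from
  identical inputs are byte-identical, and the serialized stream (magic
  "LPMH", version, layout flag, scheme, length-prefixed little-endian
  components) is the in-memory representation.

## The synthetic SPSS generator

`syntheticSpss(nKmers, k, nStrings, seed)` draws strings with independent
uniform bases under a global distinct-k-mer constraint: each string grows
base by base, candidates are tried in random order, and a base whose new
k-mer already exists is rejected (with a full re-draw of the string in the
vanishingly rare dead-end case).  For 4^k >> n this produces i.i.d.-uniform
DNA conditioned on k-mer distinctness — the regime in which the closed
forms above are derived.  What it does *not* emulate about real data:
repeat structure (so xi is essentially 0 here versus 1-4% on real genomes,
and minimizer ambiguity handling is instead exercised deliberately with
short m), biased base composition, and SPSS strings that follow unitig
length distributions.  Passing tests on synthetic data therefore validate
the combinatorics and the data structures, not genome-specific space
numbers, which depend on the input's repeat content.

Default study conditions used by the test suite: density, locality and
type-census measurements run on a single-string SPSS of 10^6 k-mers with
k = 31, m = 21 (w = 11); the space trend is measured at k = 31, 47, 63
with m = 21, 26, 28 (m-per-k choices typical for human-scale
inputs, keeping m near log4 of the input length); minimal-perfection and locality properties run over 20 fixtures
with n from 10 to 10^5 and k in {15, 31, 63}.  Statistical bands are 4
binomial standard deviations: deterministic checks with negligible
false-failure probability at these counts.

## Known limitations

* Forward strand only: no canonical (strand-symmetric) minimizers.
* The minimizer hash treats m-mers as bytes; 2-bit packing would halve
  hashing work for large m but is an internal change of the serialized
  format, not of the contract.
* Construction is single-threaded and in-memory.
* The fallback is a single flat MPHF; the recursive scheme with growing
  minimizer lengths would reduce its size on repeat-heavy genomes.
* Absolute bits/k-mer on real genomes depend on the inner MPHF constant
  (b ~ 3.7 here versus ~2.3-2.5 for state-of-the-art inner MPHFs) and on
  xi; the package reproduces trends and guarantees, not published
  genome-specific space figures.

## Session info

```{r}
sessionInfo()
```
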