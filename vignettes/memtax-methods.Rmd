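---
title: "MEM-based taxonomic classification over kernels and minimizer digests: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MEM-based taxonomic classification over kernels and minimizer digests: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtax)
```

## Overview

`memtax` classifies DNA reads against a taxonomy by maximal exact matches
(MEMs) instead of fixed-k k-mers. The collection of reference genomes is
concatenated in left-to-right taxonomy order, each genome terminated by a
`$`, and indexed with an augmented FM-index. For every MEM of a read the
index reports the text positions of the MEM's *first* and *last*
occurrence; counting `$` separators before those positions converts them
to a genome range `[first, last]`, whose two end leaves define an LCA
subtree of the taxonomy. Because an FM-index over a large collection is
expensive, the same machinery runs over three lossy representations —
an order-`kmax` first-or-last-occurrence kernel, a minimizer digest, and
a kernel of a digest — trading accuracy for index size.

This vignette records the algorithmic conventions, the tunable
parameters, the design decisions taken where the design was genuinely
open, and what the synthetic evaluation does and does not show.

## Index conventions

All rows, text offsets and genome indices are 0-based; intervals
`[lo, hi]` are inclusive. The suffix array covers the `n` suffixes of
the `$`-terminated concatenation, with end-of-string comparing smaller
than every symbol (an implicit end-of-file character realised as rank 0
during sorting, not stored as an extra row); the BWT is cyclic,
`BWT[i] = text[(SA[i] - 1) mod n]`. Under this convention the BWT of
`ACAT$` is `T$CAA` and the whole-text interval of a 45-character
collection is `[0..44]`. Symbol order is `$ < # < A < C < G < T`; digest
modes use `$ < run-symbol < dense digest codes ascending`.

One consequence of the cyclic wrap row is worth recording: backward
steps through a `$` symbol may miscount occurrences when genomes sort
differently from their `$`-successors. Query patterns never contain `$`
(reads are plain DNA, digested reads are digest codes), so no
read-facing operation is affected; the test suite verifies backward
search only for separator-free patterns, which is the entire query
surface.

Construction is pure R: prefix-doubling suffix-array construction on top
of base `order()` (radix sort), LCP by chunked vectorised comparison of
adjacent sorted suffixes, rank via cumulative occurrence tables, and
PSV/NSV/range-minimum by vectorised scans. These are exact plain-array
implementations chosen because the package's test surface is exact
equivalence with naive oracles at moderate scale, not bit-level space
optimisation; succinct structures would change none of the answers.

## The MEM table

Matching statistics are computed right to left. The invariant is the
interval and depth of the longest suffix-context currently matched;
prepending the next read character is one backward step. When the step
fails, the match is contracted to the longest prefix that *is* preceded
by that character somewhere in the text: the nearest BWT occurrences of
the character before/after the interval bound two candidate depths
(`min LCP(p+1..lo)` and `min LCP(hi+1..q)`), the larger wins, and
PSV/NSV around the leftmost LCP minimum of the winning side give the
enclosing interval, after which the step is guaranteed to succeed. On a
tie between the two sides the earlier (smaller-SA) side is used; either
side yields the same depth, and the intervals reconverge at the next
step — the brute-force equivalence tests cover this. A MEM starts at
read position `i` when `MS[i] >= 1` and the match cannot be extended
left (`MS[i-1] <= MS[i]`).

`min_mem_length` defaults to 1: the MEM definition admits length-1
matches, and the read-level verdict depends only on the *longest* MEMs,
so short MEMs change nothing unless they are all a read has. The
parameter exists because length-1 MEMs are reporting noise at scale.

## Kernels

The order-`kmax` kernel keeps exactly the characters lying inside the
first or the last whole-collection occurrence of at least one distinct
`$`-free `kmax`-mer, plus every `$`; each maximal omitted run is
replaced by a single `#`, except runs adjacent to a `$`, which are
dropped outright (queries cannot span a `$`, so nothing is lost). For
every `k <= kmax` this preserves the k-mer set and the genome of each
k-mer's first and last occurrence, which is precisely what the
`[first, last]` classification consumes — matches longer than `kmax`
are what the kernel sacrifices.

Two boundary decisions: `kmax`-mers never span a `$` (occurrences are
counted over the whole concatenation), and genomes shorter than `kmax`
are kept verbatim, so k-mer preservation still holds up to the genome
length for such genomes. A maximal omitted run of length 1 is still
replaced by a `#` (the kernel may not shrink locally); the uniform rule
keeps the construction order-independent.

## Minimizer digests

With parameters `k` (minimizer width) and `w` (window size, in k-mer
positions) and hash `h`, position `j` is selected iff some window of `w`
consecutive k-mer positions containing `j` has its leftmost minimum of
`h` at `j`. The default scheme is the affine hash
`h(x) = (2544 x + 3937) mod 8863` on the base-4 value `x` of the 3-mer,
with `w = 10`. The scheme constructor checks `gcd(a, m) = 1` whenever
`4^k <= m`, so the hash is injective on k-mers and ties inside a window
can only come from equal k-mers; the leftmost-minimum rule is applied
literally.

Decisions around the edges:

* Sequences with fewer than `w` k-mers use a single window covering all
  their k-mers — the window formula is vacuous there, but every
  non-empty sequence must digest deterministically.
* Digest characters are dense ranks of the underlying k-mer value among
  the k-mers actually selected somewhere in the collection, not raw
  hashes: identity of digest characters is then collision-free for any
  `k`, with the hash used only for selection. The printable rendering
  (consecutive ASCII from 37, covering a 64-symbol alphabet within
  ASCII 37..100) is presentation only.
* A read is digested with the collection's scheme and alphabet; selected
  k-mers never seen in the collection digest map to `NA` and break
  matches, which is what makes empty (false-negative) MEM ranges
  possible in digest modes.
* Boundary minimizers of a substring pattern need not be minimizers of
  the enclosing text, so digest-mode matching is approximate for
  arbitrary substrings; for a full-genome pattern the digest equals the
  genome's digest block exactly (tested). MEM positions/lengths in
  digest modes are in digest characters; recorded per-genome minimizer
  positions let the MEM table also report approximate source offsets.

A useful size intuition: consecutive selected positions are at most `w`
apart (every window contains a selected position), and can be as close
as 1, so a pair of adjacent minimizers spans as few as `k + 1 = 4`
source characters under the default scheme; the acceptance script
measures this minimum by randomized search.

Kernels of digests run the identical kernelization over the digest
alphabet with a dedicated run-replacement symbol, combining both
mechanisms: kernelization exploits repetition while the digest keeps the
effective pattern length per symbol high even at small `kmax`.

## Classification

Against the source genome `g`, a MEM's range is `TP` iff it is exactly
`[g, g]`; `FP` iff non-empty and excluding `g`; `VP` iff it contains `g`
and at least one other index; `FN` iff empty. Membership is integer
membership in the inclusive range `[first, last]` — the range may
overstate the true occurrence set (genomes strictly between the first
and last need not contain the MEM); that is inherent to reporting only
range endpoints and is the intended evaluation. A read is a true
positive iff *all* of its longest MEMs (ties included) are TP; each
positional MEM counts independently even if two tied MEMs map to the
same range. An aggregate diagnostic label (majority verdict among the
longest MEMs, `FN` for an empty table) is reported alongside, but only
`is_true_positive` feeds the headline rate. LCA queries use
depth-aligned pointer walking — exact and ample for taxonomies at this
scale; an Euler-tour/RMQ structure could stand behind the same contract
for very large trees.

## Synthetic fixture and read simulation

The fixture emulates the *shape* of a large rRNA reference collection
(many related sequences under a taxonomy) at roughly 1/1000 scale: a
random binary topology, a uniform random root sequence, and independent
per-site substitution at a fixed `divergence` rate along every branch;
leaves become genomes, concatenated in left-to-right leaf order so that
adjacent genomes are phylogenetically close. The standard evaluation
fixture is 50 taxa x 1000 bp at divergence 0.05, with 20 reads per
taxon of 200 bp at 1% substitution error — sizes chosen so the whole
four-mode evaluation runs in about a minute on one core while leaving
every trend measurable. Reads take a uniform start within a single
genome (they never straddle a `$` boundary, by construction of the start
range) and carry exactly `round(error_rate * length)` distinct
substituted positions — a deterministic per-read mutation load, reading
"1% of the bases" literally rather than as a Bernoulli rate. Query
timing is reported but never asserted: it is hardware-dependent.

What the fixture does *not* emulate: real taxon sampling density (some
clades heavily sequenced, others sparse), indels and structural
variation, sequence composition bias, and reverse-strand reads
(canonical strand-min minimizers are out of scope). Passing trends on
the fixture therefore show that the machinery orders the modes as
expected when relatedness decays with tree distance — not that the
absolute true-positive rates transfer to any particular real database.
Serialized sizes are those of this package's plain-array layout (bytes
per symbol, 4-byte integers), so only *relative* comparisons between
modes are meaningful.

## Numerical and degenerate-input choices

* Degenerate IUPAC codes in references are replaced by a pseudo-random
  base drawn from the code's allowed set, seeded per record from the
  record's name and position: the alphabet stays at four letters, and
  the replacement is reproducible and independent of the caller's RNG
  state. How real pipelines handle non-ACGT reference characters varies;
  this is this package's documented choice.
* Read symbols outside the pattern alphabet give `MS = 0` at that
  position and reset the match, consistent with FM-index semantics.
* Equal LCP values in a range-minimum resolve to the leftmost position;
  contraction ties prefer the previous-occurrence side.
* The divergence parameter of the fixture accepts 0 (identical genomes)
  up to, but excluding, 1.
* All randomness (fixture, simulator, degenerate-base replacement) is
  seeded explicitly, and generator functions restore the caller's RNG
  state.

## Known limitations

* Pure-R construction is comfortable up to collections of a few hundred
  thousand characters; it is not engineered for full-database scale, and
  no succinct/compressed structures (r-index, grammar-compressed suffix
  trees, LZ-based indexes) are provided.
* Only substitution errors are simulated; indel-bearing or long reads
  would shorten MEMs in ways the evaluation does not model.
* Digest-mode document ranges are approximate for arbitrary substring
  patterns (boundary-minimizer effects); the package verifies exactness
  only for full-genome patterns and otherwise relies on the verdict
  classes to absorb the noise.
* The first-occurrence-only kernel variant and Kraken-style per-k-mer
  LCA voting are intentionally not implemented; the MEM range plus LCA
  of its endpoints is the classification primitive throughout.
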