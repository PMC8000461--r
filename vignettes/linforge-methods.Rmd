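---
title: "Methods: incremental LIN assignment and ANI matrix inference"
author: "linforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: incremental LIN assignment and ANI matrix inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linforge)
```

## The model

`linforge` maintains a growing collection of prokaryotic genome
assemblies in which every genome carries a Life Identification Number
(LIN): an integer vector indexed by an ordered scheme of ANI thresholds.
The defining property is prefix-wise similarity encoding — two genomes
share a LIN prefix through every position whose threshold their ANI
reaches, and diverge at the first position whose threshold exceeds it.
Because each new genome is placed by a single precise ANI computation
against its nearest stored neighbour, the collection accumulates exactly
one alignment-based measurement per genome (after the first), and the
LIN topology plus those measurements determine a complete pairwise
matrix.

The procedure assumes that genome similarity in the collection is
locally tree-like: the nearest neighbour found by sketch search is a
good anchor, and similarity to the rest of its LINgroup is summarised by
the branch structure. Where that assumption fails — reticulate
similarity, heavy horizontal transfer, sets whose true ANI structure is
far from ultrametric — inferred values can depart from directly computed
ones. This is an inherent property of sequential assignment, not a bug:
the founding computation that split two branches stands in for every
later cross-branch pair, so cross-group values visibly merge onto few
distinct numbers. The package reproduces this merging deliberately and
reports, on request (`inferPairwise(..., detail = TRUE)`), which rule
produced each value.

## Schemes and exact threshold arithmetic

A `LINScheme` stores thresholds on an integer grid with 1e-5 percent
resolution. Grid construction (`buildScheme`) computes
`start + step * 0:n` in integer units rather than by repeated floating
addition, so a 0.1-step never drifts and `sharedDepth()` classifies
boundary ANI values deterministically: an ANI exactly equal to a
threshold *shares* that position (comparison is `<=`).

Four schemes are built in: the 20-position scheme (`lin20`, 70% to
99.999%, positions `A`..`T`, genus- to strain-level), `lin300`
(70–99.9 by 0.1), `lin3000` (70–99.99 by 0.01) and `lin_fine`
(70–99.99999 by 0.00001). The `lin_fine` grid arithmetically contains
3,000,000 positions; a figure of 300,000 is sometimes quoted for a
scheme with these endpoints and step, but those parameters imply
3,000,000 points, and this implementation follows the stated
start/stop/step rather than silently adjusting either number. Custom
schemes below 70% ANI are permitted with a warning: below ~70% ANI the
measure no longer reflects evolutionary relationships, so such positions
are advisory only.

## Sketching

Signatures are bottom-n MinHash sketches of canonical k-mers: every
k-mer window is skipped if it contains a non-ACGT character (dropped,
never substituted — substitution would make signatures depend on an
arbitrary recoding), canonicalised as the lexicographic minimum of the
k-mer and its reverse complement, and hashed with MurmurHash3
(x64_128, first half, seed 42). Hashes are truncated to 53 bits so they
are exactly representable as R doubles; at genome scale
(≤ 10^7 distinct k-mers) the extra collision probability is
negligible (< 10^-2 per pair of genomes' unions, and any collision
perturbs a 2,000-hash sketch by at most one member). Signatures are
therefore *not* hash-compatible with other sketching tools; only the
statistical behaviour is equivalent.

The Jaccard estimator is the merged bottom-n rule: with
`U` = the `min(n, |A ∪ B|)` smallest hashes of the union of sketches
`A` and `B`, the estimate is `|U ∩ A ∩ B| / |U|`. Unlike the naive
intersection-over-union of two sketches this is an unbiased estimate of
the true Jaccard of the full k-mer sets, and it reduces to the exact
value once `n` covers the union (asserted in the tests). Sketch
defaults are k = 21 and k = 51 with n = 2,000: short k-mers retain
sensitivity at low ANI, long k-mers resolve high ANI, and both are kept
per genome so each search stage can use the appropriate one.

## The classification brackets

The first search stage compares the query's k = 21 sketch against one
representative per 95%-level LINgroup and brackets the best Jaccard
`J`: above 0.2475 the query is inside that group; between 0.0025 and
0.2475 it shares at least the first (70%) LIN position; at or below
0.0025 it is novel. The two cutoffs are empirical calibrations of
Jaccard-at-k=21 against ANI (0.2475 ↔ 95%, 0.0025 ↔ 70%) adopted as
named configuration constants (`jaccardUpper`, `jaccardLower` in
`linforgeConfig()`); they are not derivable from a formula and are kept
verbatim rather than re-fit, since re-deriving them would require a
large reference corpus and would change the method's published
operating point. Both comparisons are strict on the upper side
(`J > cutoff`), so a value exactly at a cutoff falls into the lower
bracket; the acceptance script locates the switch points by bisection
to confirm the constants.

Ties — two representatives or two members at the same Jaccard — resolve
to the lowest insertion order, everywhere, so a store rebuilt in the
same order is bit-identical.

## Fragment ANI and the built-in aligner

ANI follows the fragment convention: the query is cut per contig into
consecutive 1,020 nt windows (trailing remainder kept), each fragment's
best local alignment against the subject is found, hits are retained iff
coverage > 30% *and* identity > 70% (both strict — a hit at exactly the
cutoff is discarded), and the one-way ANI is the mean retained identity.
The reported value is the mean of the two directions; if either
direction retains nothing, the pair has "no significant similarity",
which is a distinct outcome (`NA`), never a numeric 0.

The aligner is built in: exact-match seeding on 12-mer words indexed
over the subject, then, for every seeded diagonal, the maximal-scoring
ungapped segment (match +1, mismatch −1) by Kadane's algorithm, on both
strands of the fragment, best hit per fragment with ties to the lowest
subject coordinate. Identity is matches over alignment columns and
coverage is columns over fragment length, matching the BLAST
percent-identity convention the fragment-ANI definition inherits.
Extension is ungapped rather than gapped-banded: the simulator's
ANI-accuracy fixtures are substitution-only by design (below), where
per-diagonal Kadane is exact, and the hit contract (best local hit,
identity, coverage) is independent of the backend, which is isolated
behind `oneWayANI()` so a gapped or external aligner could be
substituted without touching any caller. Consequences worth knowing:
indel-rich pairs fragment their alignments across diagonals and the
reported identity is conservative there, and the maximal-segment rule
trims mismatch runs at segment ends, a bias we measured at under 0.02
percentage points at 5% divergence (the parameter-recovery tests bound
the total error at ±0.5 points across rates 0.5%–5%).

Random unrelated genomes cannot pass the filters: a spurious seeded
diagonal yields a short perfect segment whose coverage is far below
30%, so such pairs correctly report no significant similarity.

## Assignment, allocation and the store

`assignLIN()` copies the subject's LIN through `sharedDepth(ani)`
positions, places `allocateNumber()`'s result — the smallest
non-negative integer unused at that position under that exact prefix —
at the next position, and zero-fills the rest. Smallest-unused (rather
than a running counter) makes allocation reproducible and independent
of deleted or replayed history. Two edge cases are deliberate:

* ANI at or above the top threshold (e.g. re-adding an identical
  genome) copies the subject's LIN wholesale. There is no position left
  to individualise, so LINs are not unique identifiers; genome ids are.
* A bracket that promises similarity but whose precise ANI comes back
  empty demotes the genome to novel with a warning — the sketch
  calibration and the aligner disagreed, which is worth auditing but
  must not halt an ingest.

The store realises a small relational contract (genome, taxonomy,
scheme, LIN, ANI tables keyed by genome id and scheme name) as an
in-memory environment persisted to a directory of TSV tables — an
embedded, single-writer design; a database server adds operational
convenience, not semantics. Signatures live in a LINgroup-organised
layout: one JSON signature file per genome under
`signatures/groups/<prefix>/`, with the first member of each 95%-level
LINgroup copied to `signatures/representatives/`. The grouping level
(95% by default) is configurable (`groupingANI`) for collections whose
expected similarities sit elsewhere.

## Matrix inference semantics

For a pair without a direct record, the LINs diverge at position *p*.
Each of the two numbers at *p* was created by a founding event; the
recorded ANI of the *later* founding event is propagated to the pair.
When the later founder's subject carried the other branch's number this
is exactly the cross-branch computation; when its subject sat in a
third branch the same record is still used as the best available
spanning measurement, and it provably lies in the divergence bracket
`[threshold(p-1), threshold(p))` because the founder allocated at *p*.
An alternative semantic — returning the threshold of the last shared
position — is retained as the fallback when no founding record exists
(only possible for first-position novel founders, where the value falls
back to the threshold, or to 0 when nothing is shared). Propagation is
the primary rule because it reproduces the observed merging behaviour
of sequentially assigned collections; the threshold rule alone would
quantise every inferred value onto the scheme grid.

`completeLinkage()` delegates to `stats::hclust` on `100 − ANI`
(cross-checked in the tests against a naive O(n³) agglomerative
oracle), and `mantelTest()` implements the permutation test directly —
Pearson correlation of upper triangles, simultaneous row/column
permutations, `p = (1 + #{r_perm ≥ r_obs}) / (permutations + 1)`,
default 999 permutations, seeded — and is cross-checked against an
independent implementation and an exhaustive permutation oracle.

## The simulator

`randomGenome()`/`evolveGenome()`/`makeClade()` provide seeded fixtures
with known truth. Substitutions hit sites independently and always
change the base, so with zero indels the true-alignment identity is
exactly `1 − (#substituted)/L` and the analytic expectation
`(1 − r)` per edge composes multiplicatively along tree paths — the
expected-identity matrix returned with every clade is exact, not
approximate. Indels (geometric lengths, mean 2) are available but
default to 0: with indels the analytic oracle becomes approximate, so
indel runs are only used for monotonicity-style assertions. The
simulator emulates divergence by point process only — no gene content
differences, repeats, rearrangements or horizontal transfer — so passing tests
demonstrate correct recovery of substitution-driven divergence, not
robustness to every feature of real assemblies (real genomes also
differ in shared-content fraction, which depresses Jaccard at fixed
ANI; the bracket calibration absorbs this in practice).

Default test and acceptance problem sizes are 15–50 kb genomes and
≤ 12-genome clades — large enough that a genome holds tens of
fragments and sketches fill to capacity (binomial error on a
2,000-hash sketch is ~1%, and a 30 kb pair bounds the ANI standard
error near 0.1 points), small enough that the whole suite replays in
well under a minute. These sizes are the package's own fixture choice;
the pipeline itself has no lower or upper genome-size assumption beyond
`length ≥ 10 ×` the fragment length for meaningful ANI.

## Known limitations

* Inferred (non-direct) values inherit the founding computation of a
  divergence event; within a bracket they can be off by up to the
  bracket width for genuinely non-tree-like pairs. This is the price of
  one computation per genome.
* Insertion order changes LIN digits (not divergence brackets); stores
  are reproducible only under the same insertion order, which the CLI
  records in a manifest.
* The ungapped aligner under-reports identity for indel-rich pairs;
  substitute a gapped backend when assemblies are expected to differ
  structurally within fragments.
* No re-assignment exists: once placed, a LIN is permanent even if a
  later genome would have been a better anchor.
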