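# linforge

Incremental genome similarity encoding with Life Identification Numbers
(LINs) for prokaryotic genome assemblies.

## The problem

Genome-based classification of prokaryotes rests on Average Nucleotide
Identity (ANI): the query genome is cut into consecutive 1,020 nt
fragments, each fragment is locally aligned against the subject genome,
alignments with over 30% coverage and over 70% identity are retained, and
ANI is the mean identity of the retained alignments (reported here as the
average of the two directions). Precise fragment-based ANI is accurate but
expensive: a complete similarity matrix for *n* genomes needs
*n*(*n*−1)/2 alignment-scale comparisons, and every newly sequenced
isolate added to a collection re-opens the whole computation.

`linforge` is for microbiologists and bioinformaticians who maintain
growing genome collections and need complete, highly resolved ANI
matrices without quadratic alignment cost. It combines:

* **MinHash sketches** (bottom-*n* signatures of canonical k-mers,
  k = 21 and 51, n = 2,000 hashes) for fast nearest-genome search, and
* **one precise fragment-based ANI computation per added genome**,
  against the single most similar stored genome.

The sequentially computed ANI values are encoded as **LINs**: a LIN is a
vector of non-negative integers, one per position of an ordered scheme of
ANI thresholds (e.g. the 20-position scheme `A`..`T` spanning 70% to
99.999%). Two genomes share a LIN prefix exactly as deep as their
similarity reaches, so the stored LINs plus the *n*−1 recorded ANI values
suffice to infer every remaining pairwise ANI — the full matrix from one
alignment-based computation per genome.

## The algorithm in brief

For each new genome *G*<sub>Query</sub>:

1. Sketch *G*<sub>Query</sub> at k = 21 and k = 51.
2. Compare the k = 21 sketch against the representative (first member) of
   every existing 95%-level LINgroup. With the best Jaccard estimate *J*:
   *J* > 0.2475 → the query belongs to that 95%-level LINgroup;
   0.0025 < *J* ≤ 0.2475 → it shares at least 70% ANI with that group;
   *J* ≤ 0.0025 → no stored genome reaches 70% ANI (novel).
3. Within the winning LINgroup, rank all members by Jaccard (k = 51
   inside a 95% group, k = 21 otherwise); the best member is
   *G*<sub>Subject</sub>.
4. Compute reciprocal fragment-based ANI between *G*<sub>Query</sub> and
   *G*<sub>Subject</sub> — the only alignment-scale step.
5. Copy *G*<sub>Subject</sub>'s LIN through the last position whose
   threshold ≤ ANI, place the smallest unused number at the next
   position, pad with zeros. Novel genomes get a fresh number at the
   first position.

`fullMatrix()` then fills every pair: directly recorded values pass
through; any other pair diverges at some LIN position, and the recorded
ANI of the founding event that created the later branch at that position
is propagated to the whole pair.

## Worked example

Simulate a three-genome clade with known divergence (two close relatives
plus one more distant), build a store, and infer the matrix. The same
flow is available from the shell via the `inst/cli/linforge` script
(`linforge simulate | init | add | matrix | compare | status`).

```r
library(linforge)

spec <- cladeSpec(list(rate = 0, children = list(
  list(rate = 0.005, name = "s1"),
  list(rate = 0.005, name = "s2"),
  list(rate = 0.03,  name = "far"))),
  genomeLength = 15000, seed = 4)
paths <- writeClade(makeClade(spec), "clade")

store <- createStore()
for (p in paths) addGenome(store, p)
#> add s1: bracket=first_genome subject=- J=NA ANI=NA LIN=0_0_0_0_0_0_0_0_0_0_0_0_0_0_0_0_0_0_0_0
#> add s2: bracket=same_f_group subject=s1 J=0.691 ANI=98.94101 LIN=0_0_0_0_0_0_0_0_0_0_1_0_0_0_0_0_0_0_0_0
#> add far: bracket=same_f_group subject=s1 J=0.305 ANI=96.48312 LIN=0_0_0_0_0_0_0_1_0_0_0_0_0_0_0_0_0_0_0_0

similarityValues(fullMatrix(store))
#>        s1       s2      far
#> s1  100.00000 98.94101 96.48311
#> s2   98.94101 100.00000 96.48311
#> far  96.48311 96.48311 100.00000
```

Reading the output: `s1` seeds the store with the all-zero LIN. `s2`
lands in the same 95%-level LINgroup (J = 0.691 > 0.2475), its ANI to
`s1` is 98.94% — between the 98.5% and 99% thresholds — so it shares
positions A–J and takes a new number at K. `far` is also in the group
(J = 0.305) at 96.48% ANI, diverging at position H. Only two ANI
computations were performed, yet all three pairwise values are present;
the `s2`–`far` value (96.48) is inferred from `far`'s founding
computation. The simulated truth is 99.0% for `s1`–`s2` and 96.5% for
the other pairs — both recovered to within a few hundredths.

Downstream, `completeLinkage()` clusters the matrix (distance
100 − ANI), `exportDendrogram()` writes Newick, and `mantelTest()`
computes seeded Mantel/Pearson correlations between matrices.

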