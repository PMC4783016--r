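---
title: "Network-based OTU clustering with a calibrated k-mer prefilter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based OTU clustering with a calibrated k-mer prefilter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otunet)
```

## The problem

High-throughput 16S rRNA surveys produce large sets of amplicon reads that
must be grouped into operational taxonomic units (OTUs) — clusters of reads
within a fixed pairwise dissimilarity, conventionally 3% for a species-like
and 5% for a genus-like resolution — before diversity can be analyzed.
Exact pairwise dissimilarity requires a Needleman–Wunsch (NW) global
alignment per pair, which is quadratic in the number of reads and
prohibitive at survey scale. otunet implements a two-pass strategy: a cheap
k-mer distance, computed on integer-coded word profiles, prunes the
all-pairs space down to a sparse candidate network; greedy peeling of that
network produces initial clusters; and a refinement pass re-examines only
the cluster seeds and leftover singletons at the exact alignment threshold.
The package assumes its input has already been quality-trimmed,
error-corrected and chimera-checked; it performs no quality control.

## The procedure

`otu_cluster()` runs six stages, each independently exposed:

1. **Dereplication** (`dereplicate()`). Byte-identical reads collapse to
   one representative with an abundance count. Duplicates carry real signal
   — an abundant exact sequence is strong evidence for a biological
   template — so abundances feed seed selection below, and the duplicates
   are restored into the final OTUs (`rehydrate()`).

2. **k-mer transformation** (`build_codebook()`, `encode_kmer_profile()`).
   Every distinct A/C/G/T word of length *k* (default 6) receives a small
   integer code, assigned dynamically in first-encounter order. Distance
   computation then compares sorted integer vectors rather than strings.
   This is a pure re-labelling: the suite verifies, by property test
   against a direct string-counting implementation, that it never changes
   any distance. Words containing ambiguity codes (`N`, IUPAC letters) are
   skipped — they receive no code and contribute nothing to shared counts.

3. **Threshold calibration** (`determine_kmer_threshold()`). The user
   thinks in alignment dissimilarity (3%); the prefilter works in k-mer
   distance. A random sample of unique sequences (default at most 1000,
   seeded) is taken, both distances are computed for all sampled pairs, and
   the k-mer threshold is set to the 0.99 quantile of the k-mer distances
   among pairs whose NW distance is within the target. The high quantile
   buys near-zero prefilter false negatives at the cost of a few extra
   candidate edges. With fewer than 50 qualifying pairs a least-squares
   line of k-mer on NW distance is evaluated at the target instead, and if
   even that is degenerate the function stops rather than silently
   mis-calibrating. `--kmer-threshold` / `kmer_threshold=` bypasses
   calibration entirely.

4. **Initial network and peeling** (`run_pair_tasks()`,
   `build_network()`, `peel_clusters()`). All unique-sequence pairs are
   evaluated with the k-mer distance; pairs at or below the calibrated
   threshold become edges of an undirected network (the dense matrix is
   never stored). The most connected node — by *abundance-weighted degree*,
   the summed abundance of its neighbors plus its own abundance minus one —
   becomes a seed, claims its direct neighbors as a cluster, and the
   cluster is removed; this repeats until only zero-degree nodes remain,
   which are recorded as singletons.

5. **Refinement** (`refine()`). Seeds and singletons form the candidate
   set; NW distances are computed for all candidate pairs, and a refined
   network keeps pairs within the user threshold. Peeling this network
   yields the final clusters: each refined seed claims its refined-network
   neighbors plus every not-yet-assigned leaf of the initial network
   attached to the seed or to one of those neighbors. Assignment is
   greedy — once claimed, a node leaves both networks — so earlier, larger
   clusters win contested leaves, and weighted degrees are recomputed after
   every peel.

6. **Output** (`write_outputs()`). Three files: per-OTU members FASTA,
   representative (seed) FASTA, and a size table, plus a calibration TSV
   and a JSON run manifest from the command-line interface. OTUs are named
   `OTU_0001, ...` by decreasing size with ties broken by seed read id.

### Parallel execution contract

The all-pairs space of `n` sequences is linearized (`index(i,j) =
j(j-1)/2 + i`, filling the triangle top-to-bottom then left-to-right) and
cut into fixed-size chunks. The default *granularity* of 2000 pairs per
task is the empirically favorable middle ground between scheduling
overhead (finer) and load imbalance (coarser); both `granularity` and
`workers` are exposed. Chunk results are merged into the edge store as
each task completes, in chunk order, never in one bulk step at the end.
The correctness contract — verified by the suite — is that the edge set,
and hence every downstream result, is bit-identical for every worker
count and granularity. Multi-host distribution is out of scope; the
worker pool is local (forked processes).

## The distances

**k-mer distance.** For profiles of sequences $x, y$:
$$d_k(x,y) = 1 - \frac{\sum_w \min(c_x(w), c_y(w))}{\min(L_x, L_y) - k + 1}$$
clamped to $[0,1]$. The denominator is the word capacity of the shorter
sequence; skipped ambiguous words reduce only the numerator. The formula
lives in one function so an alternative normalization can be swapped in;
$k$ is configurable because 6 is a convention, not a derived quantity.

**NW dissimilarity.** Optimal global alignment under match $+1$, mismatch
$-1$, linear gap $-2$ (all configurable), with terminal gaps free by
default: amplicon reads differ in length, and end-gap-free scoring is what
makes "3% dissimilarity" behave sensibly for reads covering slightly
different spans. Distance is $1 - \text{identical}/\text{counted}$ columns,
where interior gap columns count as non-identical, terminal-gap columns
are excluded, and a column is identical only for equal unambiguous
nucleotides (N–N is a mismatch).

Two policies deserve explanation because the conventional definitions are
silent on them:

- **Minimum-overlap guard.** Under free end gaps, the optimal alignment of
  two *unrelated* sequences is frequently a short spurious perfect overlap
  (a dozen matching bases with everything else hanging off the ends),
  which would report two random 450-mers as 0% dissimilar. If the counted
  columns span less than `min_overlap_frac` (default 0.5) of the shorter
  sequence, the pair is reported maximally dissimilar. This mirrors the
  coverage thresholds of mainstream clustering tools and is inert when
  terminal gaps are counted. An alignment with no counted columns at all
  (a pure stagger) is likewise distance 1.

- **Ties.** Several alignments can attain the optimal score, and they do
  not always share one distance (`"AGT"` vs `"AT"` has co-optimal
  alignments at distances 1/3, 1/2 and 1). The implementation is
  deterministic: arguments are canonicalized (shorter, then
  lexicographically smaller, first) so the distance is exactly symmetric,
  the traceback prefers diagonal over up over left, and among end cells the
  corner is preferred. The test suite checks the score against exhaustive
  enumeration of all alignments and requires the reported distance to be
  attained by an optimal alignment.

## The synthetic mock community

`mock_community()` emulates the kind of even-composition mock community
used to benchmark clustering accuracy: `n_strains` center sequences of 450
bp (the typical 454 amplicon length) drawn uniformly and re-randomized
until every center pair is at least 10% dissimilar; per strain an equal
number of reads derived by i.i.d. substitutions (0.5% per base) and
single-base indels (0.05% per base); and 25% of reads replaced by exact
copies of earlier same-strain reads, matching the 20–37% duplicate
fractions seen in real pyrosequencing surveys. Everything is driven by one
seed and is exactly reproducible.

What it does *not* emulate: 16S sequence conservation (real strains share
conserved blocks; random centers are far more divergent than real
congeners), platform-specific error profiles such as 454 homopolymer
errors, chimeras, and abundance skew. Passing the recovery tests therefore
shows that the pipeline is correct under its stated model — well-separated
strains with small within-strain noise — not that it resolves the hardest
real-data cases, where taxa straddle the threshold.

The analytic check `expected_within_divergence()` (substitution rate plus
indel rate, ≈ 0.0055 at defaults) is compared against the observed mean
read-to-center NW distance in the suite.

## Accuracy evaluation

Against a read-to-strain truth table, every pair of labeled reads falls
into one of four classes: same strain and same OTU (TP), different strain
in one OTU (FP), same strain split across OTUs (FN), and the rest (TN).
Precision is $TP/(TP+FP)$, recall $TP/(TP+FN)$, combined by the
recall-weighted F-measure
$F_\beta = (1+\beta^2)PR/(\beta^2 P + R)$ with $\beta = 2$ by default —
the "F-measure II" convention; $\beta$ is exposed because the plain
harmonic mean ($\beta = 1$) is one flag away. The implementation uses the
per-(OTU, strain) contingency table with pair-count binomials and is
verified against brute-force pair enumeration. One caution: pair-counting
precision is not monotone under cluster splitting (splitting a mixed OTU
can remove proportionally more TPs than FPs), so precision comparisons
between very different cluster granularities deserve care.

## Numerical and design choices

- Distances are compared with `<=` at thresholds; the k-mer threshold from
  calibration is clamped to $[10^{-6}, 1]$.
- Seed selection ties break to the smallest node index; OTU naming ties
  break by seed read id; both make repeated runs byte-identical.
- In refinement, only non-candidate nodes can be absorbed through
  initial-network edges. If candidate seeds could be claimed that way,
  their own unprocessed leaves could be orphaned; restricting absorption
  to leaves guarantees that every unique sequence lands in exactly one
  final OTU, which the code asserts.
- Candidate weighting in refinement uses read abundance only, not initial
  cluster size; the switch point is `refine()`'s `abundance` argument if
  the other convention is ever wanted.
- Calibration runs on dereplicated sequences: duplicate pairs sit at
  distance (0, 0) and carry no information about the mapping.
- The calibration sample, the only stochastic element of the pipeline, is
  drawn under a private RNG stream (`rng_seed`, default 42) that never
  perturbs the caller's `.Random.seed`.
- `k` must not exceed the shortest read; empty inputs, duplicate read
  ids, empty sequences, self-loop edges and unassigned uniques are hard
  errors, not warnings.

## Problem sizes used by the tests

The suite validates the transformation-neutrality contract on 1000 random
pairs, the alignment against exhaustive enumeration on 500 short pairs,
scheduler partitions up to n = 2000, worker/granularity invariance on a
500-read community (workers 1/2/4 × granularity 100/2000), recovery on
communities of 3–10 strains across five seeds, and the evaluator against
brute force on 200 random partitions. These sizes were chosen to exercise
every contract at realistic read lengths while keeping the default test
run a matter of minutes; the method itself has no size-dependent logic
beyond the chunked scheduler.

## Known limitations

- Quadratic pair space: the prefilter reduces alignment work, not the
  k-mer distance work itself.
- A single global dissimilarity threshold is a convention, not biology;
  taxa near the threshold can split or merge either way, as the packaged
  noisy fixture (2% read noise against a 3% threshold) demonstrates.
- The greedy most-connected-seed rule is order-dependent by design;
  contested leaves go to the earlier (better-connected) cluster.
- Only linear gap penalties are offered; affine gaps and banded or
  vectorized alignment are out of scope.
- The worker pool is single-host; fault tolerance and cross-host data
  distribution are not implemented, only the deterministic-merge contract
  that would make such a distribution safe.
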