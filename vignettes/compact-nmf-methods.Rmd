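---
title: "Methods: compacted KL-NMF consensus subgrouping of copy-number profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compacted KL-NMF consensus subgrouping of copy-number profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnmf)
```

This vignette is the package's account of its statistical machinery: the
model and its assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic generator does and does not emulate,
and the numerical and design choices made where the design was genuinely
open.

## The model

Discrete copy-number calls are treated as counts.  A probe's call is split
into two non-negative features — a loss channel and a gain channel — with
severities 0 (normal), 1 (heterozygous loss / gain), 2 (homozygous
deletion / amplification) and 0.5 in the loss channel for copy-neutral
LOH.  Two channels are necessary because the factorization objective,

$$D(V\,\|\,WH)=\sum_{i\mu}\Big(V_{i\mu}\log\tfrac{V_{i\mu}}{(WH)_{i\mu}}
  -V_{i\mu}+(WH)_{i\mu}\Big),$$

is the (generalized) Kullback–Leibler divergence, the maximum-likelihood
objective when entries are Poisson; it is asymmetric, so a single feature
running from 0 (deletion) to 4 (amplification) would implicitly prefer one
aberration direction.  Within each sample and probe at most one channel is
nonzero by construction.

`nmf_factorize()` minimizes $D$ by the standard multiplicative updates
($H$ first with the current $W$, then $W$ with the fresh $H$), which never
increase the divergence and converge to a stationary point.  The
optimization is local and the problem is non-identifiable, so all
downstream inference is built on many seeded restarts rather than on any
single run.

## Compaction

CN matrices at array resolution are wide (hundreds of thousands of
columns) but highly redundant: aberrations are segmental, so neighbouring
probes carry near-identical columns.  `build_partition()` exploits this
with one greedy left-to-right pass per (channel, chromosome) block: the
first unassigned column seeds a bin, and each later unassigned column of
the block joins it if (a) its probe ordinal is within `window` of the
seed's and (b) its Hamming distance *to the seed column* is at most
`delta`.  `compact_columns()` then sums each bin into one column.

Summing is the essential point.  If $P$ partitions the columns and
$V'_{\cdot b}=\sum_{j\in P_b}V_{\cdot j}$, a factorization $(W,H')$ of
$V'$ expands to the full column space by dividing each bin's $H'$ column
by its bin size (`expand_h()`), and for bins of identical columns
$D(V\|W\,\tilde H)=D(V'\|WH')$ exactly — so at `delta = 0` the compact run
*is* the full run, only cheaper, and at small `delta` it approximately
minimizes the divergence to the full matrix.  The alternative of keeping
one representative column per bin (`reduce_standard()`) optimizes the
wrong objective — the divergence to a submatrix — and `run_comparison()`
measures how much full-matrix accuracy that costs (several-fold at the
thresholds where compaction is still essentially lossless in our
validation runs).

## Consensus clustering and rank selection

Each restart assigns sample $i$ to its largest $W$-row entry (ties to the
lowest index).  Per-run labels are permutation-ambiguous, so runs are
aggregated by co-membership: $C_{ij}$ is the fraction of runs clustering
$i$ and $j$ together.  The final subgroups cut the dendrogram of
$1-C$ (average linkage) at $k$; the consensus matrix is already a robust
summary, so the linkage choice has little leverage (it is configurable).
`stability_curve()` checks whether the number of restarts sufficed, as the
RMS difference between prefix consensus matrices and the all-runs matrix
(with a consecutive-prefix variant also available).

For the number of subgroups, `rank_report()` tabulates per rank:

* $S_{\text{mean}},S_{\text{median}},S_{\max}$ — the intra-cluster
  similarity family: per cluster, the mean consensus over its unordered
  sample pairs (singletons count 1 by the self-pairing convention, and can
  be excluded; the max variant deliberately scores the single most robust
  subgroup and ignores inter-cluster structure);
* the cophenetic correlation of the consensus dendrogram;
* the mean silhouette width on $1-C$.

No single criterion is privileged in principle — the measures capture
different aspects and should be read together.  The *reported default*
recommendation is the argmax of $S_{\text{mean}}$ (ties to the smaller
rank).  We chose this over the cophenetic argmax after observing that on
strongly structured data the cophenetic coefficient saturates: when the
consensus matrix is near block-diagonal at every candidate rank, all
cophenetic values crowd within $10^{-3}$ of 1 and their ordering is noise,
while $S(k)$ still degrades cleanly when the rank over- or under-splits
the planted structure.  The cophenetic criterion remains available via
`rank_report(criterion = "cophenetic")`.

External validation of a clustering uses `fisher_exact()`, an exact
contingency-table independence test computed by full enumeration of all
tables with the observed margins under the multivariate hypergeometric
null, summing the probabilities of tables no more probable than the
observed one (the probability-ordering two-sided convention, the same
convention as `stats::fisher.test`).  Enumeration is guarded by a table
cap; Monte-Carlo approximation for large tables is out of scope.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `delta` | `"auto"` = $\lceil 0.01\,m\rceil$ | mismatching samples | columns differing in at most 1% of samples are treated as equivalent; at $m=533$ samples this is 6 |
| `window` | 500 | probes (ordinal gap to the bin seed) | keeps every genomic region represented in the compacted matrix instead of letting one bin swallow distant look-alikes |
| `runs` / `T` | 300 (pipeline), 50 (fitting front-end) | restarts | stability of the consensus matrix typically plateaus by a few hundred runs; check with `stability_curve()` |
| `max_iter` | 2000 | update steps | safety cap; fits on compacted matrices usually converge in well under 500 steps |
| `tol` | $10^{-6}$ | relative divergence improvement per step | stops when one full update improves the objective by less than 0.0001% |
| `linkage` | `"average"` | — | no Euclidean-geometry assumption on $1-C$ (as Ward would make); choice has little effect on consensus input |
| epsilon floor | $10^{-12}$ | — | floors $W$, $H$ and the $(WH)$ denominators; multiplicative updates cannot revive exact zeros, and the floor prevents 0/0 |

Initialization is uniform on $(0,1]$ from an explicit integer seed; every
function that consumes randomness takes a seed and restores the caller's
RNG state, so entire pipelines are reproducible bit-for-bit from one base
seed (restart $t$ uses seed `base_seed + t - 1`).

## Numerical and edge-case conventions

* $0\log 0 = 0$ in the divergence; an exactly zero $(WH)$ entry against
  $V>0$ reports `Inf` (the limiting value) rather than an error.
* Hamming comparison is exact: 0, 0.5, 1 and 2 are four distinct values.
* Bin membership is tested against the seed column only — deterministic,
  $O(n\cdot\text{bins})$, and it bounds the within-bin diameter by
  $2\delta$; the seed is also the representative kept by the baseline
  reduction.  Columns never merge across channels or chromosomes, even at
  distance zero.
* In the keep-one-column baseline's full-matrix evaluation, the
  representative's $H$ column is replicated to every bin member *without*
  division: the dropped columns were never seen by that optimizer, and
  each is modeled by its representative's profile.
* Cluster ids are renumbered by decreasing size, so "cluster 1" is always
  the largest; ties keep first-seen order.
* Degenerate inputs fail fast: missing calls, negative copy numbers,
  unsorted probes, all-zero $W$ rows, constant dissimilarities for the
  cophenetic coefficient, $k=1$ silhouettes.

## The synthetic generator

`synthetic_spec()` / `generate_cn()` plant subgroup structure the way real
cohorts display it: each group carries contiguous per-chromosome
aberration blocks (a channel, a severity, a penetrance), and background
noise flips isolated probes to a random severity-1 state.  Contiguous
blocks are what give the feature matrix the column redundancy the
compaction step exploits.  The default design — 3 groups × 20 samples,
4 × 500 probes, two 150-probe blocks per group at penetrance 0.9,
background 0.02 — is a desk-scale analogue of a several-hundred-sample
250K-probe cohort, chosen so that the full validation suite (including a
10-master-seed rank-recovery experiment with 50 restarts per rank and the
compact-versus-baseline ratio grid over $\delta\in\{0,1,2,5\}$ and
$k\in\{2,3,4\}$) completes in minutes.

What the generator does *not* emulate: array-level intensity noise and
waviness, GC bias, segmentation artifacts, correlated noise along the
genome, unbalanced group sizes, or subgroups defined by partially
overlapping aberrations.  Passing the recovery tests therefore shows the
pipeline is correct and well-calibrated under clean segmental signal; it
does not certify performance on real arrays, where upstream calling
quality dominates.

## Limitations

* The Poisson/KL objective is for discrete severities; continuous data
  would need a Gaussian-type objective and a modified expansion identity.
* The greedy seed-based binning is order-dependent and not an optimal
  partition; it is the documented trade-off for determinism and speed.
* Rank recommendation is a reporting default, not a decision rule; the
  measures disagree precisely in the interesting borderline cases.
* `fisher_exact()` is enumeration-only and refuses tables beyond its cap
  rather than approximating.
* Survival analysis of the emitted subgroups is intentionally out of
  scope; the label tables are written so standard survival tooling can
  consume them directly.

```{r quick-tour, eval = FALSE}
# end-to-end on synthetic data
cohort <- generate_cn(synthetic_spec(seed = 42))
fit <- cnmf(cohort, k = 3, runs = 50)
summary(fit)
rank_report(fit$compact, 2:5, T = 50)
```
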