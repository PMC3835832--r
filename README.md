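# cnmf: subgroup discovery from DNA copy-number profiles by compacted NMF

`cnmf` finds subgroups of patients that share DNA copy-number (CN)
aberration patterns — a common goal in the study of heterogeneous cancers,
where subgroups defined by recurrent gains and losses can differ in
molecular subtype, outcome and treatment response.  Its input is a matrix
of discrete probe-level CN calls (from SNP arrays, aCGH or sequencing,
already segmented and called), optionally with copy-neutral LOH flags; its
output is a consensus clustering of the samples together with rank-selection
diagnostics.

## The method

Samples-by-probes calls are first split into **two non-negative features
per probe** (a loss channel and a gain channel), encoding severity: normal
is 0, heterozygous loss / gain is 1, homozygous deletion / amplification is
2, and copy-neutral LOH is 0.5 in the loss channel.  The asymmetric split
is needed because the factorization assumes Poisson-generated counts, and a
single signed feature would order losses below gains.

The core model is non-negative matrix factorization under the generalized
Kullback–Leibler (I-)divergence

$$D(V\,\|\,WH)=\sum_{i\mu}\Big(V_{i\mu}\log\frac{V_{i\mu}}{(WH)_{i\mu}}
  -V_{i\mu}+(WH)_{i\mu}\Big),$$

minimized by the classic multiplicative updates, where $V$ is the
$m\times n$ feature matrix, $W$ ($m\times k$) holds sample weights and $H$
($k\times n$) holds component profiles.

High-resolution platforms make $n$ far too large to factorize directly, so
similar columns are **compacted** first: a greedy pass per channel and
chromosome groups columns into bins whenever a column's Hamming distance to
the bin's seed column is at most $\delta$ (default: 1% of the sample count)
and it lies within a 500-probe window of the seed.  Binned columns are
**summed** into one column, $V'_{\cdot b}=\sum_{j\in P_b}V_{\cdot j}$.  The
point of summing rather than discarding is that the NMF run on $V'$ then
minimizes the divergence to the *full* matrix: the fitted compact $H$
expands back to all original columns (each bin column divided by its bin
size), and at $\delta=0$ the compaction is lossless — the same optimum as
factorizing $V$ itself.  The package also implements the keep-one-column
baseline (`reduce_standard()`), whose degraded full-matrix accuracy
`run_comparison()` quantifies.

Because the optimization is local and non-identifiable, the clustering is
not read off a single run: many seeded restarts each assign samples to
their dominant component, the co-clustering fractions form a **consensus
matrix**, and hierarchical clustering (average linkage on $1-C$) cuts it
into $k$ subgroups.  The number of subgroups is chosen by weighing the
**intra-cluster similarity** $S(k)$ (the mean over clusters of the average
within-cluster consensus; also median and max variants, the max flagging a
single robust subgroup), the cophenetic correlation and the mean
silhouette — `rank_report()` tabulates all of them.  Associations of the
subgroups with external categorical annotations (e.g. molecular subtypes)
are assessed with an exact contingency-table test (`fisher_exact()`).

## Worked example

A synthetic cohort with three planted subgroups (60 samples, 2,000 probes,
two 150-probe aberration blocks per group at penetrance 0.9, 2% background
noise):

```r
library(cnmf)
cohort <- generate_cn(synthetic_spec(seed = 42))
fit <- cnmf(cohort, k = 3, runs = 50)
fit
#> Consensus compact-NMF fit
#>   60 samples, 4000 features compacted to 634 bins (delta = 1, window = 500)
#>   rank k = 3, 50 restarts (seeds 1..50)
#>   subgroup sizes: 20, 20, 20
#>   best full-matrix divergence: 9230.08
summary(fit)
#> Consensus compact-NMF: k = 3
#> Subgroup sizes: 20, 20, 20
#> Per-subgroup consensus similarity: 0.998, 1.000, 0.989
#> S_mean = 0.996, S_median = 0.998, S_max = 1
#> Cophenetic correlation: 1
#> Mean silhouette: 0.996
#> ...
table(predicted = predict(fit), truth = cohort$labels)
#>          truth
#> predicted  1  2  3
#>         1 20  0  0
#>         2  0 20  0
#>         3  0  0 20
```

The 4,000 encoded features collapse to 634 bins at the automatic threshold
($\delta=\lceil 0.01\cdot 60\rceil=1$); the three planted subgroups are
recovered exactly, each with near-unit within-subgroup consensus.
`plot(fit)` draws the ordered consensus heatmap, `coef(fit)` returns the
factor matrices (with `H` expanded to the original probes),
`rank_report()` scans candidate ranks, and `run_subgrouping()` /
`inst/cli/cnmf` drive the same pipeline from configuration files and the
shell.

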