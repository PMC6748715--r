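# nemoclust

Neighbourhood-based multi-omics clustering of patient cohorts, with native
support for **partial datasets** — cohorts in which some samples were never
measured on some omics — and no imputation anywhere.

## Who this is for

Cancer-genomics and systems-biology analysts who have several omic matrices
(gene expression, DNA methylation, miRNA expression, ...) for one cohort and
want molecular subtypes that use all of the data, including the samples that
only have a subset of the omics. The usual workarounds — restricting to the
complete-data subcohort, or imputing entire missing omics — discard
information or invent it; this package does neither.

## The method

For each omic *l* with data matrix *X<sub>l</sub>* (*p<sub>l</sub>* features ×
*n<sub>l</sub>* samples), similarity between samples *i*, *j* is a
locally-scaled RBF kernel

&nbsp;&nbsp;&nbsp;&nbsp;*S<sub>l</sub>*(i,j) = 1/(2π σ<sub>ij</sub>) · exp( −d²(i,j) / 2σ²<sub>ij</sub> )

where d is Euclidean distance and the bandwidth
σ²<sub>ij</sub> = ⅓·( mean<sub>r∈η<sub>i</sub></sub> d²(i,r) +
mean<sub>r∈η<sub>j</sub></sub> d²(j,r) + d²(i,j) )
adapts to the local sampling density via each sample's k-nearest-neighbour
set η. Similarities are then renormalised within neighbourhoods into a
*relative similarity*

&nbsp;&nbsp;&nbsp;&nbsp;*RS<sub>l</sub>*(i,j) = S(i,j)/Σ<sub>r∈η<sub>i</sub></sub>S(i,r) · I(j∈η<sub>i</sub>) + S(i,j)/Σ<sub>r∈η<sub>j</sub></sub>S(r,j) · I(i∈η<sub>j</sub>)

— a sum of random-walk transition distributions, which makes values
comparable across omics with different scales. The integrated network
averages the *RS<sub>l</sub>*: over all *L* omics on full data, or, on
partial data, over only the omics in which both samples of each pair were
measured (every pair must share at least one omic; this holds whenever one
omic covers the whole cohort). The network is partitioned by
normalised-Laplacian spectral clustering; the number of clusters is
argmax<sub>i</sub> (λ<sub>i+1</sub> − λ<sub>i</sub>)·i over ascending
Laplacian eigenvalues — an eigengap rule weighted to favour finer partitions,
never selecting fewer clusters than the plain eigengap. The default
neighbourhood size is *n<sub>l</sub>*/#clusters per omic (or
*n<sub>l</sub>*/6 when the cluster count is unknown).

## Worked example

```r
library(nemoclust)

sim <- nemo_simulate(center_spread = 5, samples_per_cluster = 30, seed = 7)
sim <- mask_partial(sim, omic = 2, theta = 0.3, seed = 7)  # 30% of samples lose omic 2
fit <- nemo(sim$omics, seed = 7)
summary(fit)
#> Neighbourhood-based multi-omics clustering
#>   2 omics, 60 samples (partial data)
#>   clusters: 2 (weighted eigengap); k per omic: 10, 7; seed: 7
#>   cluster sizes: 30, 30
#>   mean pairwise omic coverage: 1.49
#>   eigengap at c=2: 0.6365
#>   leading Laplacian eigenvalues:
#>     0.0000 0.0000 0.6365 0.6496 0.6998 0.7078 0.7470 0.7570 0.7719 0.7733

adjusted_rand_index(fit$labels, sim$labels)
#> [1] 1
```

The two near-zero Laplacian eigenvalues followed by a wide gap are the
spectral footprint of two well-separated clusters; the weighted eigengap
picks c = 2 and the recovered partition matches the generating labels
exactly (adjusted Rand index 1) despite 30% of samples missing the second
omic. Every fit records the neighbourhood sizes, chosen cluster count and
seed needed to reproduce it.

A missingness sweep repeats generate → mask → cluster → score over a theta
grid:

```r
theta_sweep(thetas = c(0, 0.4, 0.8), n_datasets = 3, n_repeats = 3,
            center_spread = 5, samples_per_cluster = 30, seed = 1)
#>   theta mean_ari sd_ari n_runs
#> 1   0.0        1      0      9
#> 2   0.4        1      0      9
#> 3   0.8        1      0      9
```

Survival and clinical evaluation of a clustering use `logrank_test()` and
`empirical_enrichment()` (chi-square for discrete parameters,
Kruskal-Wallis for numeric ones, with permutation-based empirical p-values
that avoid the anti-conservative asymptotic approximation).

## Command line

A thin wrapper over the same functions is installed at
`inst/scripts/nemo.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/nemo.R", package="nemoclust"))') \
  cluster --omic expr.tsv --omic meth.tsv --clusters 3 --seed 1 --out labels.tsv
```

Subcommands: `cluster`, `evaluate`, `simulate`, `sweep`. Omic files are
delimited text, features × samples, first row sample IDs, first column
feature IDs.

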