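---
title: "Methods: neighbourhood-based multi-omics clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neighbourhood-based multi-omics clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemoclust)
```

## The model

The package clusters a cohort measured on $L$ omics, each a matrix $X_l$ of
$p_l$ features by $n_l$ samples, in three phases.

**Per-omic similarity.** Within omic $l$, sample closeness is squared
Euclidean distance $d^2(i,j) = \lVert x_{li} - x_{lj}\rVert^2$ between
profiles. Let $\eta_{li}$ be sample $i$'s $k$ nearest neighbours (self
excluded). The similarity is a locally-scaled RBF kernel
$$S_l(i,j) = \frac{1}{2\pi\,\sigma_{ijl}} \exp\!\left(-\frac{d^2(i,j)}{2\sigma^2_{ijl}}\right),
\qquad
\sigma^2_{ijl} = \tfrac{1}{3}\Big(\tfrac{1}{k}\!\sum_{r\in\eta_{li}}\! d^2(i,r)
 + \tfrac{1}{k}\!\sum_{r\in\eta_{lj}}\! d^2(j,r) + d^2(i,j)\Big).$$
All three bandwidth terms are *squared* distances; the pairwise term keeps
the scale symmetric while the two neighbourhood means adapt it to local
sampling density, so dense and sparse regions of the cohort get comparable
similarity values. Similarities are then renormalised within
neighbourhoods into the relative similarity
$$RS_l(i,j) = \frac{S_l(i,j)}{\sum_{r\in\eta_{li}} S_l(i,r)}\,I(j\in\eta_{li})
 + \frac{S_l(i,j)}{\sum_{r\in\eta_{lj}} S_l(r,j)}\,I(i\in\eta_{lj}).$$
$RS_l = A + A^\top$ with $A$ row-stochastic over neighbourhoods, i.e. each
row of $A$ is the transition distribution of a random walk restricted to the
sample's $k$ nearest neighbours. This is the step that makes different omics
commensurable: whatever the raw value distributions, every sample
distributes one unit of outgoing similarity mass.

**Integration.** On full data the integrated network is the mean
$ARS = \frac{1}{L}\sum_l RS_l$ — a mixture of the per-omic transition
distributions. On partial data (some samples absent from entire omics),
each entry averages over only the omics observed for both samples,
$ARS(i,j) = |JM(i,j)|^{-1}\sum_{l \in JM(i,j)} RS_l(i,j)$ with $JM(i,j)$
the omics covering both $i$ and $j$. No cell-level missingness is accepted
and nothing is imputed; the only requirement is $JM(i,j)\neq\emptyset$ for
every pair, which holds whenever one omic (typically gene expression or
methylation) covers the whole cohort. With no missing samples the partial
average reduces exactly to the full one — the test suite asserts bitwise
agreement to $10^{-14}$.

**Partitioning.** The integrated network is clustered by
normalised-Laplacian spectral clustering: with degree matrix $D$, the
spectrum of $L_{sym} = I - D^{-1/2}\,ARS\,D^{-1/2}$ is computed, the rows of
the $n \times c$ matrix of the $c$ leading eigenvectors are renormalised to
unit length, and k-means partitions them. The number of clusters, when not
supplied, is
$$c = \arg\max_{i\in[2,\,c_{\max}]} (\lambda_{i+1} - \lambda_i)\, i$$
over ascending Laplacian eigenvalues — the classical eigengap weighted by
its index. The weighting never selects fewer clusters than the plain
eigengap (if $j < i^\*$ maximised the weighted score, its unweighted gap
would have to exceed the plain maximum) and tends towards finer partitions,
which is the behaviour wanted for subtype discovery.

## Assumptions

- Omic matrices are preprocessed (normalised, batch-corrected,
  feature-filtered) upstream; values are treated as dimensionless. An
  optional per-feature z-score (`scale_features = TRUE`) is provided but off
  by default.
- Partial data means whole-sample omic absence. An `NA` cell is an input
  error, reported with its position.
- A single $k$ per omic implicitly assumes roughly equal cluster sizes.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `k` (neighbourhood size) | $\lfloor n_l/c \rfloor$ if the cluster count $c$ is known, else $\lfloor n_l/6 \rfloor$ | the neighbourhood should approximate one cluster; 6 is a crude typical subtype count for cancer cohorts. Computed per omic from that omic's own $n_l$, floored, clamped to $[1, n_l-1]$. An explicit `k` overrides both. |
| `max_clusters` | 15 | upper end of the eigengap search; with the search starting at 2 the trivial single-cluster answer is unreachable. |
| `n_clusters` | chosen by weighted eigengap | supplying it fixes both the partition size and the default `k`. |
| k-means restarts | 20, seeded | the embedding is low-dimensional and well separated, so a modest restart count suffices; the seed makes fits reproducible. |
| `prefactor` | `"2pi"` | the kernel constant $1/(2\pi\sigma)$; a Gaussian-density variant $1/(\sqrt{2\pi}\sigma)$ is exposed as `"density"`. The constant rescales numerator and denominator of the relative similarity together wherever local scales are comparable, so the choice is inert in practice; both are kept because the convention differs across the similarity-network literature. |

## Numerical choices

- **Bandwidth floor.** $\sigma^2$ entries below $10^{-12}$ are floored (with
  a message) so duplicated samples cannot produce a zero bandwidth.
- **Neighbour ties** are broken by ascending sample index — deterministic
  across platforms.
- **$k$ rounding** is `floor`, clamped to $[1, n_l - 1]$.
- **Eigengap ties** go to the larger candidate, consistent with the rule's
  preference for finer partitions.
- **Eigenvalue convention.** The selection rule operates on eigenvalues of
  the symmetric normalised Laplacian (the same operator that drives the
  clustering), not of the raw affinity; both conventions order cluster
  structure the same way, and using the Laplacian keeps model selection and
  embedding on one spectrum. `laplacian_spectrum()` and
  `num_clusters_eigengap()` are exported separately so either convention can
  be assembled by hand.
- **Degenerate embeddings** (a zero-norm eigenvector row) and
  zero-degree samples raise errors naming the sample rather than silently
  assigning it.
- Distances are computed via the Gram-matrix identity with negative
  round-off clamped to zero and symmetry enforced; the suite checks the
  vectorised path against scalar double loops to $10^{-10}$.

## The synthetic generator

`nemo_simulate()` reproduces the structure of the package's simulation
study: a base features-by-samples matrix is drawn as per-cluster Gaussian
centers (spread `center_spread`) plus shared within-cluster noise
(`base_noise_sd`), and each signal omic adds independent per-omic Gaussian
noise (`omic_noise_sd`) — so all signal omics share one underlying
clustering. `add_noise_omic()` appends an omic of pure i.i.d. noise with no
cluster information; `mask_partial()` removes a fraction $\theta$ of
randomly chosen samples (whole columns, `round` half-up) from one omic,
defaulting to the second. Defaults are 2 clusters × 100 samples, 50
features per omic, all spreads and noise sd 1. The "easy regime" used by
the recovery checks sets `center_spread = 5`, putting expected
between-cluster squared distance an order of magnitude above within-cluster
spread so that ground-truth recovery is the correct answer, not a
statistical accident.

What the generator does *not* emulate: heavy-tailed and count-valued omics,
correlated features, unequal cluster sizes, informative missingness
(masking is uniform at random), and omics carrying *contradictory* cluster
structure. Passing the simulation checks therefore demonstrates the
machinery — kernel, integration, model selection, partial-data averaging —
under the generating model, not performance on any real cohort.

`theta_sweep()` runs the full protocol (10 independent datasets, 10 random
masks per dataset and $\theta$, cluster, score against truth by adjusted
Rand index) and reports mean and sd per $\theta$. Because the generating
cluster count is known in simulation, sweeps pass it to the fit by default,
which also fixes $k = n_l/2$ per omic.

## Evaluation statistics

`adjusted_rand_index()` implements pair-counting agreement with the
expected-index correction (closed form from the contingency table; the test
suite checks it against explicit enumeration of all sample pairs and
against an established external implementation). `logrank_test()` wraps the
multi-group logrank test (chi-square with $c-1$ df) from the survival
package. `empirical_enrichment()` associates clinical parameters with
clusters — chi-square without continuity correction for discrete
parameters, Kruskal-Wallis for numeric — but replaces the asymptotic
p-value, which overstates significance on clustered cohorts, with a
permutation p-value: cluster labels are permuted with the parameter fixed,
and $p = (1 + \#\{stat_{perm} \ge stat_{obs}\})/(1 + n_{perm})$. The
add-one correction keeps $p$ off zero (minimum $1/(n_{perm}+1)$); the
statistic only ranks permutations, so the continuity-correction choice
cancels. Defaults: 1000 permutations, seeded. Permuting cluster labels
rather than parameter values is equivalent under the null and keeps
parameter missingness patterns intact.

## Problem sizes and determinism

The shipped checks run at deliberately desk-friendly sizes: oracle
comparisons on 5–20-sample instances, recovery and sweep checks at 200
samples × 50 features per omic, and one larger smoke fit at 600 samples ×
3000 total features (the cost profile is $O(n^2 P)$ for distances plus
$O(n^3)$ for the dense eigendecomposition). Every stochastic step — center
draws, noise, masking, k-means, permutations — flows from explicit seeds
through a single derivation helper, so identical inputs and seed give
identical labels, sweep tables and simulated data; the suite asserts this
end to end. Sparse eigensolvers for large cohorts are out of scope.

## Known limitations

- The pair-coverage requirement excludes cohorts where two groups of
  samples were measured on disjoint omics.
- One $k$ per omic assumes comparable cluster sizes; strongly unbalanced
  subtypes may deserve per-sample neighbourhood sizes.
- The integrated network weights omics equally; contradictory or redundant
  omics are averaged in, not down-weighted.
- Feature importance is not provided; derive it downstream by differential
  analysis of the final clusters.
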