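---
title: "Models and methods behind bdgcoex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bdgcoex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bdgcoex` measures whether a head-to-head gene pair sharing a bidirectional
promoter is co-expressed beyond what is typical for such pairs genome-wide.
This vignette documents the models, the parameters that matter, the design
choices that were genuinely open, and the limits of what the synthetic
validation shows.

## The bidirectional-pair catalog

A bidirectional (divergent) pair is a minus-strand gene and a plus-strand
gene on the same chromosome whose transcription start sites face each other
across a short intergenic span: `0 ≤ tss(+) − tss(−) ≤ max_distance`, with
1000 bp as the default threshold. Genes enter with one representative TSS,
the 5′-most across their transcripts (minimum start on `+`, maximum end on
`-`). The 5′-most rule is the most inclusive choice for promoter proximity
and is deterministic; using per-isoform TSSs would let one gene join several
pairs with no principled way to pick one.

Two further choices were open:

* **5′-overlapping pairs are excluded.** A configuration with
  `tss(+) < tss(−)` cannot be distinguished from a small convergent pair
  using TSS coordinates alone, so the catalog requires the minus TSS at or
  left of the plus TSS. Pairs with exactly coincident TSSs (distance 0) are
  kept.
* **Greedy nearest-partner matching.** When a TSS has several qualifying
  partners, candidate pairs are accepted in order of increasing TSS
  distance, ties broken by lexicographic gene id, and a gene already in a
  pair is skipped. This makes the catalog unique, reproducible under any
  input permutation, and biased toward the tightest (most promoter-like)
  arrangement. Catalog size therefore depends on the annotation snapshot
  and on these rules; the same rules are applied to synthetic annotations
  so round-trips are exact.

## Normalization

The dropout model operates on CP10K/log1p values: each cell scaled to
10,000 total counts, then `log(1 + x)`. Per-cell library sizes are retained
so the transform can be inverted after imputation; downstream correlations
default to the inverted (count-scale) matrix, since the headline statistic
is defined on an imputed count matrix, while the log-scale matrix remains
available (`correlation_scale: log`).

## The dropout mixture

For each gene with nonzero variance, expression across cells is modeled as

$$f(x) = \lambda\,\mathrm{Gamma}(x;\alpha,\beta) +
        (1-\lambda)\,\mathcal{N}(x;\mu,\sigma),$$

the gamma component representing dropout (zeros and near-zero leakage) and
the normal component genuine expression. The per-entry dropout probability
is the gamma-component posterior. Fitting is EM with closed-form updates
for $\lambda,\mu,\sigma$ and a three-step Newton solve of the gamma shape
score equation per M-step; the compiled core is verified against a pure-R
reference implementation in the test suite. Initialization splits each gene
at its median ($\lambda_0$ = fraction below; gamma moments from the lower
half, normal moments from the upper half). Convergence is a per-gene
log-likelihood gain below `tol` (default 1e-6, `max_iter` 100); genes that
do not converge keep their last iterate and are flagged.

Numerical choices worth knowing:

* **Zeros are a point mass.** On the log scale every dropout is exactly 0,
  which no continuous density can carry. Zeros are evaluated at half the
  smallest positive value in the matrix, so the gamma component can
  concentrate there and assign dropout probability ≈ 1 to zeros of
  otherwise-expressed genes. Parameter clamps (`σ ≥ 1e-3`,
  `α ∈ [1e-3, 1e4]`, `β ∈ [1e-6, 1e8]`) keep the spike representable
  without overflow.
* **Identifiability guard.** An unconstrained two-component fit happily
  splits a unimodal gene into a lower and an upper piece. A gene's dropout
  component is accepted only if its mean lies below both $\mu - 2\sigma$
  and $\mu/2$; otherwise $\lambda$ is set to 0 and nothing in that gene is
  imputed. Constant genes are flagged and never imputed. This errs on the
  conservative side: weakly separated genes keep their observed values.

## Imputation

Entries with dropout probability above `threshold` (default 0.5, the
conventional posterior cut) are replaced by a weighted mean of the same
gene over the cell's `k_neighbors` = 20 most similar cells. Similarity is
the Pearson correlation between cells over genes confident in *both*
(dropout probability ≤ threshold in both), computed exactly for all cell
pairs via masked cross-products. Weights are `max(similarity, 0)`,
renormalized over neighbors in which the gene itself is confident; entries
with no usable neighbor are left unchanged. Confident entries are never
touched (bit-identical before/after), and imputed values are clamped at
1.5× the gene's largest confident value so a run of optimistic neighbors
cannot manufacture outliers.

This neighbor-averaging stage deliberately replaces the per-cluster
non-negative regression used by the tool it stands in for: it is simpler,
deterministic, and sufficient for rank-percentile analyses, but it will
differ entry-by-entry from that tool's output. With ≤ 10,000 cells the
computation is exact and seed-independent; the `seed` argument is reserved
for neighbor subsampling beyond that scale.

## Correlation and rank percentile

Every cataloged pair with both genes present and nonzero variance gets a
Pearson coefficient across all cells; others are flagged
(`missing_gene`/`zero_variance`) and excluded from the distribution. The
query pair's rank percentile from the top is
`100 · #{r ≥ r_query} / n_pairs`, query included. Ties count toward the
numerator — the conservative direction for "top X%" claims. Signed `r` is
the default; ranking on `|r|` is a flag. Percentiles therefore lie in
(0, 100], and a smaller value means stronger relative co-expression.

## Trend, ratio, and clustering utilities

* **Linear trend.** For `k` ordered groups (e.g. copy-number classes −1,
  0, 1, 2) the contrast uses equally spaced centered scores
  $c_i = i - (k+1)/2$: $L = \sum_i c_i \bar y_i$,
  $SE = \sqrt{\mathrm{MSE}\sum_i c_i^2/n_i}$ with the one-way ANOVA
  within-group mean square, $t = L/SE$ on $N - k$ degrees of freedom,
  two-sided p. At $k = 2$ this is exactly the pooled two-sample t-test
  (verified to 1e-10 in the tests). The degenerate all-constant, zero-trend
  case returns p = 1 rather than an error.
* **Expression ratio.** `a/b` per sample, excluding and counting samples
  with `b = 0`. With a proliferation normalizer `n` (e.g. MKI67) the ratio
  is `(a/b)/n` for samples with `n > 0`. The normalization is algebraically
  ambiguous as usually stated — dividing both `a` and `b` by the marker
  would cancel — so the `(a/b)/n` reading is implemented; per-gene
  normalization before ratioing is the documented alternative.
* **Dendrogram.** Pairwise Pearson across samples, distance `1 − r`,
  average linkage. Genes are processed in lexicographic order, making leaf
  order and tie-breaks input-order invariant; linkage heights are checked
  against a brute-force UPGMA recomputation.

## The synthetic study generator

The generator emulates the scale of a two-line single-cell study screened
against a genome-wide bidirectional catalog: defaults of ~1,500 cells and
~2,000 pairs (4,200 genes including isolated ones). Per gene, a lognormal
mean (`meanlog` 0.5, `sdlog` 1.2 — median ≈ 1.6 counts with a realistic
dynamic range); per cell, a latent log-normal fluctuation (`latent_sd` 0.8)
on which planted pairs share bivariate-normal latents with correlation ρ
(Gaussian copula) while all other genes are independent; counts are
negative-binomial (dispersion 0.3); technical zeros arrive with probability
`1/(1 + exp(a·(log mean − b)))` (`a` = 1.5, `b` = 0.5), i.e. decreasing in
gene mean, and the mask of zeroed nonzero counts is kept as ground truth.

The copula-on-latents design was chosen over correlating counts directly so
that ρ has a clean interpretation independent of NB noise: the observable
count correlation is an attenuated, monotone function of ρ (the tests
verify stability of that mapping at n = 10,000 cells). Planted-pair genes
take their mean at the 70th percentile of the gene-mean distribution
(`planted_mean_quantile`): a planted signal in a gene the simulation
happened to silence would measure the draw of the mean, not the method, so
the benchmark pins the signal in the detectably expressed regime.

What the generator does **not** emulate: batch effects, doublets, cell-type
mixture, UMI saturation, library-size structure shared across genes, or
ambient RNA. Passing the synthetic benchmarks therefore shows the pipeline
recovers planted co-expression under NB noise and mean-dependent dropout —
not that it is robust to those unmodeled artifacts in real data.

## Validation scale and determinism

The test suite validates the catalog against exhaustive O(n²) enumeration
(20 random annotations up to 500 genes), mixture recovery on 2,000-point
samples over 20 seeds (estimates within 3 Monte-Carlo SEs), planted-signal
recovery at full study scale (2,000 pairs × 1,500 cells, ρ = 0.9, 20
seeds, rank percentile ≤ 1%), imputation benefit on masked entries over 10
mid-scale seeds, and 2-block dendrogram recovery over 20 seeds. These sizes
are the package's chosen validation scale; the generator accepts larger
ones. Attenuation reduction is assessed on the log scale the imputer
operates on; masked-entry error on `log1p` counts.

Every stochastic stage is a deterministic function of its config and seed;
the pipeline writes a manifest (config snapshot, input checksums, seed,
per-stage dimensions) sufficient to regenerate every output.

## Known limitations

* The catalog cannot see 5′-overlapping divergent pairs (excluded by
  design) and inherits any TSS inaccuracies of the annotation.
* The imputer shares the usual limits of neighbor methods: with few cells,
  or genes expressed in almost no cells, it leaves entries unchanged rather
  than guess; correlations for such pairs stay attenuated.
* The conservative identifiability guard can declare a weakly separated
  low-expression gene dropout-free, leaving its zeros unimputed.
* Count-scale correlations after imputation inherit Jensen-type bias from
  averaging on the log scale before back-transforming; rank percentiles are
  insensitive to this, absolute `r` values less so.
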