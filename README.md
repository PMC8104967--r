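# bdgcoex

Head-to-head (divergent) gene pairs that share a bidirectional promoter are
a recurrent feature of mammalian genomes: two genes transcribed away from a
short intergenic region, often under common regulation. Given a gene
annotation and a single-cell RNA-seq count matrix, `bdgcoex` asks a simple
question about any such pair — say, a tumor-suppressor/oncogene pair of
interest: **is this pair co-expressed more strongly than bidirectional gene
pairs in general?**

The package is aimed at computational biologists analyzing single-cell or
bulk expression of candidate bidirectional pairs. It provides:

* **Catalog construction** — parse a GTF (or plain gene table), take each
  gene's 5′-most TSS, and enumerate divergent pairs with
  `0 ≤ tss(+) − tss(−) ≤ d` (default `d` = 1000 bp), greedily matched so
  each gene joins at most one pair.
* **Dropout imputation** — each gene's normalized expression across cells
  is modeled as a mixture
  `f(x) = λ·Gamma(x; α, β) + (1 − λ)·Normal(x; μ, σ)`,
  where the gamma component captures dropout (technical zeros). Entries
  with posterior dropout probability > 0.5 are replaced by a
  similarity-weighted average over the cell's 20 most similar cells,
  similarity being Pearson correlation over genes confidently expressed in
  both cells.
* **Genome-wide ranking** — Pearson correlation `r` for every cataloged
  pair, and the query pair's rank percentile from the top,
  `100 · #{pairs with r ≥ r_query} / n_pairs`.
* **Companion statistics** — ANOVA post-test for linear trend across
  ordered copy-number classes (contrast `c_i = i − (k+1)/2`,
  `t = Σc_i ȳ_i / √(MSE Σc_i²/n_i)`), Spearman correlation, average-linkage
  co-expression dendrograms on `1 − r`, and marker-normalized expression
  ratios.
* **A synthetic study generator** — negative-binomial counts with lognormal
  gene means, a Gaussian copula that plants latent correlations into chosen
  pairs, and logistic mean-dependent dropout, with full ground truth for
  validation.

## Worked example

Simulate a study of 250 bidirectional pairs across 500 cells with one pair
given latent correlation ρ = 0.9, then recover it:

```r
library(bdgcoex)

cfg <- simulation_config(n_genes = 600, n_cells = 500, n_bdg_pairs = 250,
                         planted_pairs = data.frame(pair = 1L, rho = 0.9),
                         seed = 42)
gtf <- tempfile(fileext = ".gtf")
make_toy_annotation(cfg, gtf)
catalog <- detect_bdg_pairs(read_gene_models(gtf), max_distance = 1000)
nrow(catalog)
#> [1] 250

sim     <- simulate_counts(cfg)
norm    <- normalize_cp10k_log(sim$matrix)
model   <- fit_dropout_model(norm)
model
#> <dropout_model> 600 genes x 500 cells; 4 constant; mean lambda 0.093

imputed <- impute_matrix(norm, model)
cors    <- pair_correlations(denormalize_cp10k_log(imputed), catalog)
correlation_distribution(cors, query = c("GPAIR0001_M", "GPAIR0001_P"))
#> <correlation_distribution> 246 pairs, median r = -0.007
#>   query GPAIR0001_M/GPAIR0001_P: r = 0.186, rank percentile 0.41% from top
```

The planted pair's correlation (0.186, attenuated from ρ = 0.9 by counting
noise and dropout) still ranks in the top 0.41% of all pairs, while the
null pairs center on r ≈ 0. The trend utility works on any ordered
grouping, e.g. expression against copy-number classes:

```r
linear_trend_test(c(2.1, 2.4, 3.0, 3.2, 3.9, 4.4, 4.1, 5.0),
                  factor(rep(c(-1, 0, 1, 2), each = 2)))
#> Linear trend across 4 groups (-1 < 0 < 1 < 2): L = 3.975, t = 6.518, df = 4, p = 0.00286
```

A command-line front end over the same functions lives at
`inst/cli/bdgcoex.R` (subcommands `run`, `catalog`, `simulate`, `impute`,
`correlate`, `rank`, `trend`, `ratio`, `cluster`), and `run_pipeline()`
executes the full catalog → ingest → impute → correlate → rank chain from a
YAML config, writing per-stage outputs and a run manifest.

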