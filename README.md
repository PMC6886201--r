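# jointDE

Joint between-sample normalization and differential expression detection
for RNA-seq count data via ℓ0-regularized regression.

## The problem

RNA-seq measures transcript abundance only *relatively*: read counts are
confounded with library size and sequencing depth, so between-sample
normalization is a prerequisite of any differential expression (DE)
analysis. Standard pipelines normalize first (CPM, TMM, upper-quartile,
median-of-ratios) and test afterwards — but normalization should rest on
the non-DE genes, whose identity is only known *after* the DE analysis.
When many genes are DE, and especially when they shift asymmetrically
(mostly up- or mostly down-regulated), scaling-factor normalization is
biased and downstream testing can fail completely.

`jointDE` instead fits both at once. For log-transformed expression
y<sub>ij</sub> of gene *i* in sample *j* it models

> y<sub>ij</sub> = α<sub>i</sub> + β<sub>i</sub><sup>T</sup> x<sub>j</sub> + d<sub>j</sub> + ε<sub>ij</sub>,  ε<sub>ij</sub> ~ N(0, σ<sub>i</sub>²),

where x<sub>j</sub> ∈ ℝ<sup>p</sup> are continuous experimental
covariates (dose, age, a biomarker level, …), d<sub>j</sub> is a
sample-specific normalization offset (d<sub>1</sub> = 0 for
identifiability) and α<sub>i</sub> a gene effect. Differential expression
is expressed through an ℓ0 penalty on the coefficients:

> min Σ<sub>ij</sub> (y<sub>ij</sub> − α<sub>i</sub> − β<sub>i</sub><sup>T</sup>x<sub>j</sub> − d<sub>j</sub>)² / 2σ<sub>i</sub>² + Σ<sub>i</sub> λ<sub>i</sub> · 1{β<sub>i</sub> ≠ 0}

(type I penalty; a type II variant penalizes only the last coordinate
β<sub>ip</sub>, testing one covariate of interest while adjusting for the
rest). Profiling out α and d reduces the problem to per-gene least-squares
solutions coupled only through δ, the precision-weighted mean coefficient;
genes are then kept or killed by an exact closed-form threshold, and δ is
found by global one-/two-dimensional grid search (multi-start local
optimization for p > 2). Gene-wise noise variances are estimated by
alternating maximum likelihood and stabilized by shrinkage toward their
mean; the penalty λ is derived from a significance level q via χ²/Gaussian
quantiles.

The package also ships the synthetic count generator (log-normal and
negative-binomial noise around a realistic depth/length/offset model) and
a replicate benchmark runner that scores DE detection by ROC AUC, so the
method's simulation behavior is reproducible end to end with no external
data.

## Worked example

```r
library(jointDE)

sim <- simulate_counts(m = 2000, n = 20, de_fraction = 0.3, up_fraction = 0.75,
                       noise = "negbinom", seed = 101)
fit <- jointde(sim$counts, sim$covariates, penalty = "type1", q = 0.01)
summary(fit)
#> Joint normalization / differential expression fit (L0 penalty)
#>   2000 genes x 20 samples, 1 covariate(s), penalty type1
#>   lambda = 3.3174 (q = 0.01, shrunk variances)
#>   selected genes: 597 (29.85%)
#>   shared slope delta = 0.2935
#>
#> Top genes by p-value:
#>    gene_id   beta   p_value selected
#>  gene_1283  4.082 1.064e-19     TRUE
#>  gene_1087  3.790 2.587e-19     TRUE
#>  gene_1635  4.178 6.262e-19     TRUE
#>   gene_773  3.788 9.410e-19     TRUE
#>  ...
#>
#> Normalization offsets d: range [-3.636, 0.200] (d[1] = 0)

compute_auc(fit$pvalues, sim$de_labels)
#> [1] 0.9874
cor(fit$d, log(sim$library_sizes) + sim$sample_offsets)
#> [1] 0.9999
```

30% of the genes were simulated as DE and the fit selects 29.85% at
q = 0.01; the estimated offsets d̂<sub>j</sub> recover each sample's true
log depth (library size plus simulated offset) essentially perfectly, and
ranking genes by the post-normalization p-values separates DE from null
genes with AUC 0.987.

The fitted object supports `coef()`, `fitted()`, `residuals()`,
`predict()` (gene-level predictions at new covariate values, without the
sample offsets) and `plot()` (p-value histogram and offset profile).

A command-line interface with `simulate`, `fit`, `test` and `benchmark`
subcommands is installed under `exec/jointde`; all subcommands are thin
wrappers over the functions above and write TSV/JSON with a provenance
header line.

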