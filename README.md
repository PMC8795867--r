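# srdml

Sparse-representation discriminative metric learning for content-based image
retrieval (CBIR), aimed at grayscale medical images such as brain MRI slices.

Given labeled feature vectors (512-dimensional GIST descriptors by default),
`srdml` jointly learns a sparse-coding dictionary **B** (unit-norm atoms), the
coding coefficients **Y**, and a positive semidefinite Mahalanobis metric
**M** over those coefficients, by minimizing

```
||X − BY||²_F + α·Tr(YᵀLY) + β·Σ g(1 − ℓᵢⱼ(τ − d²_M(yᵢ, yⱼ))) + γ·||Y||²_F
        s.t.  M ⪰ 0,  ||b_k||₂ = 1
```

where `L` is the graph Laplacian of a k-NN similarity graph over dictionary
atoms, `g(y) = log(1 + e^{θy})/θ` is the generalized logistic (softplus)
loss, `ℓᵢⱼ = ±1` marks same/different-class pairs, and
`d²_M(u, v) = (u − v)ᵀM(u − v)`. Similar pairs are pushed below the threshold
`τ − 1` and dissimilar pairs above `τ + 1`. Optimization alternates a
closed-form dictionary update, a graph rebuild, closed-form per-column
coefficient updates, and a PSD-projected gradient step on the metric; the
joint objective is non-increasing by construction. Databases are then ranked
against a query by `d²_M` between coding coefficients, and rankings are scored
with mAP and Prec@n under a label-stratified k-fold protocol.

The methods vignette (`vignettes/srdml-methods.Rmd`) documents the model,
every tunable parameter, and the numerical design choices.

## Worked example

```r
library(srdml)

# labeled synthetic features with planted sparse structure (3 classes x 60)
syn <- generate_synthetic(synthetic_spec(seed = 202))
syn$features
#> <feature_matrix> 64 features x 180 images, 3 class(es)

# fit: dictionary size defaults to n, here we train a compact model
hp  <- srdml_hparams(K = 12, T_max = 12, ksvd_iters = 5, seed = 202)
fit <- srdml_fit(syn$features, hp)
fit
#> <srdml_model> d = 64, n = 180, K = 12 | 12 outer iteration(s)
#>   objective 2650.16 -> 164.801

glance(fit)[, c("objective", "fidelity", "pairwise", "metric_rank", "tau")]
#> # A tibble: 1 × 5
#>   objective fidelity pairwise metric_rank   tau
#>       <dbl>    <dbl>    <dbl>       <int> <dbl>
#> 1      165.     27.6     32.6          12  8.54

tidy(fit)          # per-iteration objective breakdown (autoplot(fit) to plot)

# retrieve: rank the training database against a held-out-style query
code   <- encode_query(syn$features$X[, 1], fit$B, hp$gamma)
ranked <- rank_database(code, fit$Y, fit$M,
                        db_ids = fit$ids, db_labels = fit$labels,
                        query_label = syn$features$labels[1])
head(ranked, 3)
#> # A tibble: 3 × 6
#>    rank index distance id      label relevant
#>   <int> <int>    <dbl> <chr>   <int>    <int>
#> 1     1     1    0.657 img0001     1        1
#> 2     2     6    0.733 img0006     1        1
#> 3     3    21    0.745 img0021     1        1

# evaluate: stratified 5-fold cross-validation (metrics in percent)
cv <- cross_validate(syn$features, srdml_hparams(T_max = 12, ksvd_iters = 5,
                                                 n_pairs = 2000, seed = 202),
                     n_folds = 5, seed = 1)
cv[cv$fold == "mean", c("query_class", "map", "prec10", "prec20")]
#> # A tibble: 4 × 4
#>   query_class   map prec10 prec20
#>   <chr>       <dbl>  <dbl>  <dbl>
#> 1 1             100    100    100
#> 2 2             100    100    100
#> 3 3             100    100    100
#> 4 all           100    100    100
```

A query's `map` of 100 on this fixture means every same-class image ranks
ahead of every other-class image; on noisier data (`noise_sigma = 0.3`) the
cross-validated mAP measured by `scripts/acceptance.R` drops to roughly
85–90.

GIST extraction from images: `extract_batch(paths)` (or
`extract_gist(matrix)`) returns the 512-dimensional descriptors as a
`feature_matrix`; `write_features()`/`read_features()` persist them as CSV.

A command-line interface wrapping these functions ships at
`inst/cli/srdml.R` (subcommands `extract`, `simulate`, `train`, `retrieve`,
`evaluate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","srdml.R",package="srdml"))')" \
    simulate --out feats.csv --seed 5
```

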