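# tdfe — tensor-decomposition feature extraction for paired omics layers

`tdfe` selects phenotype-associated features jointly from two omics layers
measured on the same samples — classically mRNA and miRNA expression from a
tumor/normal cohort. Instead of testing each feature against the class
labels (which over-selects: supervised per-feature tests routinely pass
ten thousand genes at FDR 0.01 in a tumor/normal contrast), it extracts a
small number of latent components shared by the two layers without looking
at the labels, uses the labels only to *identify* the component that
separates the classes, and selects the features that dominate that
component. The package is aimed at transcriptomics analysts who want an
unsupervised, integrated alternative to per-feature differential
expression.

## The method

Let `a_ij` be expression of mRNA `i` in sample `j` (N × M) and `b_kj`
expression of miRNA `k` in sample `j` (K × M). Conceptually the two layers
form a three-way tensor

    x_ijk = a_ij · b_kj            (N × M × K)

which is far too large to store for genome-scale N·M·K. `tdfe` never
materializes it: summing over samples gives

    x_ik = Σ_j a_ij · b_kj  =  A Bᵀ      (N × K)

and the SVD of this collapsed matrix,

    x_ik = Σ_l λ_l · u_li · v_lk ,

yields, for each component `l`, one singular vector per layer (`u` over
mRNAs, `v` over miRNAs). Projecting each layer back onto its vector gives
per-sample component coordinates

    p^A_lj = Σ_i a_ij u_li ,   p^B_lj = Σ_k b_kj v_lk .

Components are screened with a Welch t-test of `p^A_l` and `p^B_l` between
the two classes and with the Pearson correlation between the two
projections; the working component minimizes the worse of the two t-test
P-values (or is fixed manually). Features are then scored on that
component's singular vector: each entry is standardized by the vector's own
standard deviation and `(u_li/σ)²` is referred to the upper tail of a
χ²(1 df) distribution; after Benjamini–Hochberg correction, features with
adjusted P < 0.01 are selected.

The package also implements the PCA variant of the same scheme (per-layer
gram-matrix eigenvectors as feature scores, sample loadings screened the
same way), a supervised Welch t-test baseline, all-pairs mRNA–miRNA
Pearson correlation of the selected features, and cross-dataset
concordance testing of two selection sets over a shared feature universe
(2×2 confusion table, two-sided Fisher exact test, cross-product and
conditional-MLE odds ratios).

## Worked example

A built-in generator produces paired layers with a planted class-driven
signal, so the whole pipeline runs without any download:

```r
library(tdfe)

ds <- generate_dataset()       # reference conditions, fixed seed
ds
#> synthetic_dataset: 2000 x 60 (mRNA), 300 x 60 (miRNA), 30 case / 30 control
#>   planted signal: 50 + 20 features, effect 2, noise sd 1

r <- run_tdfe(ds$layer_a, ds$layer_b, ds$annotation)
round(r$diagnostics[1:3, ], 4)
#>   l t_p_rows t_p_cols     pcc  pcc_p
#> 1 1   0.8320   0.9498 -0.1377 0.2941
#> 2 2   0.0000   0.0000  0.9952 0.0000
#> 3 3   0.9227   0.9847  0.9913 0.0000
r$component
#> [1] 2
```

Component 1 captures the shared baseline expression profile (it does not
separate the classes); component 2 separates cases from controls in both
layers (Welch P ≈ 3e-70 and 2e-58) and its two projections correlate at
r = 0.995 — so it drives selection:

```r
sum(r$scores_a$selected); sum(r$scores_b$selected)
#> [1] 50
#> [1] 19
recovery_metrics(r$scores_a$id[r$scores_a$selected], ds$truth_a)
#> $precision [1] 1   $recall [1] 1   $f1 [1] 1
```

All 50 planted mRNAs (and 19 of 20 planted miRNAs) are recovered with no
false positives. Selected features can then be cross-correlated:

```r
sub_a <- ds$layer_a[r$scores_a$id[r$scores_a$selected], ]
sub_b <- ds$layer_b[r$scores_b$id[r$scores_b$selected], ]
pairs <- pairwise_correlations(sub_a, sub_b)
#> pairwise_correlations: 950 pairs, 473 significant positive,
#>   477 significant negative (alpha = 0.01)
```

The same pipeline is available from the shell via `exec/tdfe`
(`simulate`, `run --method td|pca|ttest`, `concordance`, `pairs`), reading
tab-separated expression matrices — plain features × samples TSV or GEO
series-matrix files — and writing score tables plus a `summary.json`.

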