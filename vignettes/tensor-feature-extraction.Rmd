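---
title: "Integrated feature extraction from paired omics layers: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated feature extraction from paired omics layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdfe)
```

## The model

Two expression layers are measured on the same M samples: layer A
(`a_ij`, N features, typically mRNA) and layer B (`b_kj`, K features,
typically miRNA). The integrated analysis treats their per-sample outer
products as a three-way tensor `x_ijk = a_ij b_kj`. A full Tucker/HOSVD
factorization of that tensor — a core tensor plus one orthogonal factor
matrix per mode — is neither computable nor needed at genome scale
(N·M·K easily exceeds 10^9 entries). `tdfe` therefore works with the
sample-collapsed matrix

$$x_{ik} = \sum_j a_{ij}\, b_{kj} = (A B^\top)_{ik},$$

whose SVD

$$x_{ik} = \sum_l \lambda_l\, u_{li}\, v_{lk}$$

supplies, per component, one feature vector in each layer's space. The
core tensor of the full Tucker form is never computed, and no accuracy
claim is made about it: the collapsed matrix *is* the object being
factorized, and every downstream quantity (projections, scores) is defined
from it. Sample projections

$$p^{A}_{lj} = \sum_i a_{ij} u_{li}, \qquad
  p^{B}_{lj} = \sum_k b_{kj} v_{lk}$$

re-introduce the sample mode: a component whose projections differ between
phenotype classes *in both layers*, and whose two projections correlate
with each other, represents coordinated mRNA–miRNA variation aligned with
the phenotype. The assumptions, made explicit:

* class-relevant variation is (approximately) rank-one across the two
  layers — a single latent factor loads on a subset of features in each
  layer and on the class contrast across samples;
* the collapsed matrix is dominated by few components, so the class
  factor is not buried in noise components;
* singular-vector entries of a non-signal feature behave like draws from
  a zero-centred Gaussian, which underlies the χ² scoring below.

## Feature scoring

For the chosen component, each feature entry is standardized by the
standard deviation of its own vector and `(u_{li}/σ)²` is referred to the
upper tail of χ² with 1 degree of freedom — the distribution of the square
of a standardized Gaussian, which is the only df consistent with squaring
a single standardized coordinate. Raw P-values are Benjamini–Hochberg
adjusted; features with adjusted P strictly below `alpha` (default 0.01)
are selected.

Two consequences worth knowing:

* **σ mode.** `σ` defaults to the sample (n−1) standard deviation;
  `sd_mode = "population"` uses the n denominator. On genome-scale
  vectors the difference is negligible; it is exposed because the
  definition is otherwise ambiguous.
* **Spike-fraction ceiling.** Because σ is computed from the scored
  vector itself, k equal-magnitude signal features among m total cap
  `(u/σ)²` near `m/k`. A layer where 30% of features carry signal can
  never reach small χ² P-values; the method is built for *sparse*
  signatures (the defaults plant 2.5% and 6.7% signal features). This is
  a property of the scoring rule, not an implementation limit, and it
  explains why the miRNA layer (K = 300, 20 planted) recovers slightly
  less reliably than the mRNA layer at the same effect size.

## Component identification

Per component, the package reports Welch (unequal-variance) t-test
P-values comparing case vs control projections in each layer, and the
Pearson correlation between the two layers' projections. The automatic
rule picks the component minimizing `max(t_p_rows, t_p_cols)` — the
component must separate the classes in *both* layers — with ties broken
toward the smaller index. Manual choice (`component = 2`) is supported for
the classical workflow of fixing the component after inspecting the
diagnostics. Welch rather than pooled-variance t is used throughout:
tumor/normal designs are routinely unbalanced with unequal spread, and
Welch costs nothing when variances happen to be equal.

Sign convention: SVD signs are arbitrary, so each component is oriented to
make its largest-magnitude layer-A entry positive. All selection and
diagnostic quantities are invariant to this choice (the correlation's sign
is reported as computed under it); the convention exists purely so that
repeated runs are bit-identical.

## Normalization

Per-sample standardization (each sample column centred to mean 0 and
rescaled to sum of squares N) is defined by the PCA route and applied by
default before the tensor route as well, for a deliberate reason: the χ²
scoring assumes component entries comparable against a Gaussian null, and
raw scales (RSEM abundances vs microarray intensities) would otherwise let
high-magnitude samples dominate the collapsed matrix. The flag
`standardize = FALSE` disables it. An optional `log2(x + offset)`
transform (default off) is available for strongly right-skewed abundance
data. No quantile normalization, batch correction, or library-size scaling
is attempted — inputs are expected to be expression summaries already
processed by a standard upstream pipeline.

With standardized layers the leading component of the collapsed matrix
captures the shared baseline expression profile (features' mean levels),
which is why the class-driven factor typically appears as component 2.
This is the expected phenomenology on real cohorts as well, but it is not
guaranteed — hence the diagnostics-driven component choice instead of a
hard-coded index.

## The synthetic generator

`generate_dataset()` emulates exactly the structure the method assumes:
per-feature baselines `μ_i ~ N(μ0, baseline_sd²)`, a binary class score
`c_j = ±1`, planted signal features shifted by `δ·s_i·c_j` with random
per-feature signs, and i.i.d. Gaussian noise, independently in both
layers. Defaults — N = 2000, K = 300, 30 case + 30 control, 50 + 20
planted features, δ = 2, noise sd 1, μ0 = 5, baseline sd 1, seed
20200916 — are the package's reference conditions: a balanced desk-scale
cohort with an effect size (2 noise sd) typical of a strong
differential-expression signature, and μ0 far enough from zero that the
baseline component dominates, reproducing the component-2 phenomenology.
A lognormal option exponentiates the Gaussian field for strictly positive,
right-skewed values. An unbalanced tumor-heavy cohort (e.g. 253/71) is a
one-line configuration change; the balanced default keeps the t-test
diagnostics statistically stable at this sample size.

What the generator does **not** emulate: count noise and sequencing
depth, batch effects, correlated feature blocks beyond the single planted
factor, miRNA–target network topology, or multiple latent subclasses.
Passing the recovery tests therefore demonstrates that the implementation
extracts a planted rank-one cross-layer factor correctly and calibrates
its null — not that the method will resolve any particular real cohort,
where signal rank, confounding and normalization all intervene.

## Numerical choices

* Dense LAPACK SVD is used at all sizes. The factorization cost is
  governed by `min(N, K)` of the collapsed matrix — the smaller layer's
  feature count, typically a few hundred to a few thousand for miRNA — so
  an iterative truncated solver would add a dependency without changing
  feasibility. The contract is fixed by invariants (orthonormal factors,
  reconstruction of the collapsed matrix, non-increasing λ), not by the
  route.
* Tolerances: orthonormality and vector comparisons at 1e-8,
  reconstruction at 1e-10, brute-force oracle agreement at 1e-12;
  standardization must hold to |mean| ≤ 1e-10 and |SS − N| ≤ 1e-8·N.
* Degenerate inputs: constant sample columns standardize to all-zero with
  a warning; features with non-finite values or zero variance are dropped
  (with counts reported) before analysis; a zero-variance component
  vector is a hard error in scoring; pairs involving a zero-variance
  feature are flagged undefined and excluded from the BH grid; Welch
  features with both classes constant and equal carry NA P-values and are
  never selected; a confusion table with a zero margin yields Fisher
  P = 1 with undefined odds ratios, flagged.
* Fisher's exact test is two-sided by the probability-mass criterion
  (sum of conditional hypergeometric probabilities not exceeding the
  observed table's, with a 1e-7 relative slack against floating-point
  ties). Both the cross-product odds ratio `ad/bc` (infinite when
  `bc = 0`) and the conditional-MLE estimate are reported, because the
  two differ noticeably on tables with small selected margins.
* Selection uses a strict inequality (`adjusted P < alpha`).
* GEO series-matrix reading ingests probes as-is; collapsing probes to
  genes, and matching identifiers across platforms for concordance
  analysis, are upstream tasks — `cross_dataset_confusion()` takes
  pre-matched ID sets and errors on IDs outside the stated universe.

## Validation problem sizes

The shipped tests exercise: brute-force tensor-collapse and SVD oracles on
instances up to 8 × 6 × 7; BH against an O(m²) reimplementation on a
thousand random vectors; Fisher P against full hypergeometric enumeration
on every 2×2 table with margins ≤ 12; end-to-end recovery and null
calibration on the reference 2000/300-feature, 60-sample conditions (ten
replicates for the null). These sizes keep the whole suite under a minute
while covering every code path; the pipeline itself has no comparable
size limits (the collapsed matrix for a 19,536 × 825 cohort is an
ordinary dense matrix).

## Known limitations

* Binary designs only; no multi-class or continuous phenotypes.
* One component drives selection; signatures spread over several
  components require manual iteration.
* The χ² null is an approximation: singular-vector entries are not
  exactly Gaussian, and the null calibration shown on synthetic data does
  not certify FDR control on arbitrary real data.
* No survival analysis, enrichment analysis, or external-database
  annotation — selections are handed on as plain feature-ID tables.
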