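---
title: "Sparse factor analysis for multi-omics integration: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse factor analysis for multi-omics integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Tumor cohorts (and other multi-omics studies) measure several molecular data
types — RNA expression, copy number, protein arrays — on the same samples.
`omicsfa` models the stacked sample vector $x \in \mathbb{R}^n$ (all data
types concatenated) as a linear function of $k \ll n$ continuous latent
factors:

$$x = B^\top z + e, \qquad z \sim N(0, I_k), \qquad e \sim N(0, \Psi),$$

where $B$ is the $k \times n$ coefficient (loading) matrix and $\Psi$ is
diagonal with one variance per *data type* (all features of a type share a
residual variance). Over $N$ samples, the $N \times n$ data matrix factorizes
as $X \approx Z B$. Coefficients are made sparse with an elastic-net penalty;
the L1/L2 pair is shared by all features of a data type and reparameterized
through a per-type level $l$ and a global mixing parameter $\alpha$:

$$\lambda_1 = \alpha\, l, \qquad \lambda_2 = 10^{-6} + (1 - \alpha)\, l .$$

The $10^{-6}$ ridge floor keeps every coordinate update strictly contractive;
it is numerically invisible otherwise. $\alpha = 0.9$ (mostly lasso) is the
default.

Assumptions worth keeping in mind: all conditionals are Gaussian, so binary
data (mutations) are not modeled — associations with mutations are computed
*post hoc* with a rank statistic; there is no missing-data mechanism, and the
readers reject missing cells outright; features are mean-centered because the
model has no intercept.

## The fitting algorithm

`fit_sfa()` alternates four steps:

1. **Initialization** (`init_pca()`): $B$ is set to the top-$k$ principal
   axes scaled so the implied factor scores have unit sample variance
   ($B_{j\cdot} = d_j v_j^\top / \sqrt{N-1}$ from the SVD), with the
   largest-magnitude loading of each component made positive so runs are
   bit-reproducible. Residual variances start at the mean squared rank-$k$
   reconstruction residual per type, floored at $10^{-8}$.
2. **E-step** (`e_step()`): the exact Gaussian posterior
   $V = (I_k + B \Psi^{-1} B^\top)^{-1}$,
   $E[Z|X] = X \Psi^{-1} B^\top V$,
   $E[Z^\top Z|X] = N V + E[Z|X]^\top E[Z|X]$, followed by rescaling each
   factor column of $E[Z|X]$ to unit sample variance and conjugating
   $E[Z^\top Z|X]$ by the inverse scale. Without this rescaling the penalty
   shrinks coefficients while the factors inflate to compensate, and the
   effective penalization level drifts. The rescaling also makes
   $E[Z^\top Z|X]/N \approx I$, which the coefficient update relies on.
3. **Coefficient update** (`coordinate_descent_pass()`): one sweep of
   elastic-net coordinate descent with soft-thresholding,
   $$B_{ij} \leftarrow S\!\big(B_{ij} + \tfrac1N (E[Z|X]_{\cdot i}^\top
   X_{\cdot j} - B_{\cdot j}^\top E[Z^\top Z|X]_{\cdot i}),\,
   \lambda_{j,1}\big) / (1 + \lambda_{j,2}).$$
   Updates run factor-major; within one factor row the coordinates do not
   interact (each touches only its own feature column), so the row is
   computed vectorized with results identical to the sequential order.
   The bare $1/(1+\lambda_2)$ denominator is exact only when
   $E[Z^\top Z|X]/N = I$; this is why the rescaling step is mandatory, and
   why the sweep-monotonicity test asserts ascent of the *surrogate*
   objective the update coordinate-minimizes rather than the penalized
   log-likelihood itself (which contains $\Psi^{-1}$ the update does not see,
   and provably can decrease across a sweep).
4. **Residual variance** (`update_residual_variance()`): per type,
   $\hat\Psi_i = (\mathrm{tr}(X_i X_i^\top) - \mathrm{tr}(E[Z|X]\hat B_i
   X_i^\top)) / (n_i N)$, floored at $10^{-8}$ so exactly-reconstructed
   blocks stay valid.

Convergence is declared when the mean absolute change in the reconstruction
error $\|X - E[Z|X] B\|_F^2 / (Nn)$ over the last 10 iterations falls below
`tol` ($10^{-6}$ by default; the $Nn$ normalization makes that threshold
comparable across dataset sizes), with a hard cap of 5000 iterations.

### On reconstruction-error monotonicity

The PCA initialization is the *global optimum* of the rank-$k$ reconstruction
error, while the EM fixed point is the posterior-mean reconstruction, which
sits slightly above it (the posterior mixes factors through $V$). Any correct
implementation must therefore let the reconstruction error climb from the
initialization toward its equilibrium; with penalties the climb is larger
because shrinkage genuinely trades reconstruction for sparsity. On data
generated at a 3:1 signal-to-noise ratio the per-iteration increases are of
order $10^{-8}$–$10^{-5}$ and vanish as noise goes to zero. The acceptance
suite asserts the near-monotonicity bound on the unpenalized fit and records
the measured maximum increase; it is a property of the algorithm, not a bug
to be patched around.

## Penalty selection

`sfa_grid_search()` fits every point of a per-type level grid (default: six
log-spaced levels on $[0.01, 1]$, chosen to bracket everything from
effectively unpenalized to support-collapsing on unit-scaled data) and ranks
them by BIC, warm-starting adjacent points. Exact ties go to the sparser
model. A grid point whose fit degenerates (a penalty so strong that a whole
factor dies, making the unit-variance rescaling impossible) is reported and
excluded rather than silently regularized.

**Which likelihood goes into BIC.** The effective number of parameters is the
Tibshirani–Taylor estimate: with the rescaled factor design and the fixed
posterior moments the multi-response penalized regression decouples across
factors, and factor $i$ contributes $\sum_{j \in A_i} t_i / (t_i +
2\lambda_{2,j})$ over its active set ($t_i = z_i^\top z_i$) — the active-set
size in the lasso limit, zero in the ridge-dominated limit. For the
likelihood itself we use the *observed-data* (marginal) likelihood
$x \sim N(0, B^\top B + \Psi)$, which is what BIC is defined on. The
complete-data log-likelihood with the posterior factors plugged in is
available (`bic_score(..., likelihood = "complete")`) but is not a sound
selection criterion here: every added coefficient also shrinks its block's
fitted residual variance, so the plug-in likelihood rewards parameters at a
rate that exceeds $\log N$ (about 6.3 per coefficient at $N = 300$ on
generated data versus $\log 300 \approx 5.7$), and the criterion slides
toward the densest candidate with a false-discovery proportion near 60%.
With the marginal likelihood the selected level recovers the true support
with precision $\approx 0.85$ and recall $\approx 0.95$ under the benchmark
conditions below — the numbers are recomputed by `scripts/acceptance.R` on
every run.

The acceptance benchmark walks the six default levels as a single shared
level across data types: the generator draws every type at the same
signal-to-noise ratio and coefficient scale, so the natural small grid is
one-dimensional. The full Cartesian product (216 points) selects equivalently
along that diagonal at ~50× the cost.

## Preprocessing

- `select_top_mad_genes()` ranks genes by the raw median absolute deviation
  (no 1.4826 consistency constant — the ranking is all that matters) and
  keeps the top `count` (1000 in the intended workflow), breaking ties by
  original column order. Selection happens *before* weight multiplication.
- `apply_precision_weights()` multiplies expression by per-entry precision
  weights (e.g. from a mean–variance trend fit) and records each gene's mean
  weight for later transfer adjustment.
- `summarize_cn_regions()` reduces segmented copy number to a sample ×
  region matrix: the unweighted median of all segments overlapping the
  region by ≥ 1 bp, 1-based inclusive coordinates. No length-weighting; a
  sample with no overlapping segment for some region is an error naming the
  pair, not a silent NA.
- `scale_by_datatype_sd()` mean-centers each feature and divides each block
  by one pooled scalar SD. Per-feature scaling would erase the within-type
  variance structure that the shared per-type penalty is designed to act on
  uniformly; the single scalar only removes gross unit differences between
  platforms.

## Factor interpretation by gene-set enrichment

`run_factor_gsea()` regresses the *full* expression matrix (not only the
modeled genes) jointly on all $k$ factors, divides each gene's coefficients
by the gene's SD to obtain correlation-like scores (exactly Pearson
correlations when $k = 1$ and the factor has unit variance), ranks genes per
factor (ties broken by gene id), and scores each (set, factor) pair with the
weighted Kolmogorov–Smirnov running sum (weight exponent $p = 1$, the classic
choice). Significance comes from a *sample permutation* null: each
permutation shuffles the factor rows and reruns the entire
regression→normalization→ranking→scoring chain, because permuting samples
changes the regression, not just the scores.

Conventions, each of which matters for calibration:

- **NES** divides each ES by the mean same-sign null ES of its own pair.
- **p-values** count same-sign nulls at least as extreme *among the
  same-sign nulls*, add-one on both numerator and denominator. Counting over
  all `n_perm` nulls instead caps null p-values near 0.5 and destroys
  uniformity; with the same-sign denominator the null p-values are uniform
  to the resolution of the permutation lattice (verified by a
  Kolmogorov–Smirnov check in the acceptance suite).
- **FDR**: the default is the GSEA-style pooled tail ratio (fraction of all
  null NES beyond the observed NES over the fraction of observed NES beyond
  it, same sign, capped at 1). This estimator has no add-one regularization,
  so the most extreme of $m$ observed pairs falls below $q = 0.25$ in about
  $1 - e^{-0.25} \approx 22\%$ of *null* tables, whatever $m$ is. Where a
  null-tight decision rule matters — including the calibration checks in the
  acceptance suite — use `fdr_method = "BH"`: with the discrete permutation
  p-values (minimum $\approx 1/101$ at `n_perm = 200`) a Benjamini–Hochberg
  discovery needs several pairs at the minimal p simultaneously, which makes
  a clean table the overwhelming null outcome.
- The default report filter mirrors the FDR < 0.25 and leading-edge
  proportion < 0.5 convention. The leading-edge proportion here is the
  fraction of set members at or before the running-sum extremum (after it,
  for negative ES). Note that a sharply enriched set concentrates *all* its
  members in the leading edge and is excluded by that filter; the filter
  targets diffuse enrichments, and the NES/p columns remain the primary
  evidence.

## Transfer to new samples and platforms

`transfer_model()` extracts one data type's coefficient block with the
reference cohort's per-gene means and variances. To score a new cohort:
`adapt_coefficients()` divides each gene's coefficients by its mean
precision weight over the reference samples (undoing the weighting baked
into the fit); `harmonize_expression()` maps each modeled gene to its most
variable probe on the new platform (variance computed on the new cohort),
centers on the new cohort, and rescales each gene to the reference variance;
`project_samples()` applies the closed form

$$Z = X_{\text{mRNA}}\, B_{\text{mRNA}}^\top
  (B_{\text{mRNA}} B_{\text{mRNA}}^\top + I)^{-1},$$

which works for a full cohort or a single sample. Genes absent from the new
platform are dropped from both $X$ and $B$ with a logged count and *no*
renormalization — the projection formula has none, and the drop count is the
honest quality diagnostic. Adaptation precedes harmonization; both precede
projection.

## The synthetic generator and what passing tests mean

`generate_multiomics()` draws data exactly from the model: standard-normal
factors, per-type sparse Gaussian coefficients (a fraction $s_i$ of entries
at uniformly random positions), i.i.d. Gaussian noise. Noise is set either
directly or through a per-type signal-to-noise ratio (mean per-feature
signal variance over noise variance), so fixtures keep their meaning when
feature counts change. A master seed fans out to per-type substreams, so
adding a data type does not perturb the other types' draws.

The generator emulates the *statistical* structure the model assumes and
none of the structure real data adds: no copy-number segment geometry, no
count mean–variance trends, no batch effects, no outliers, no missing
values, no binary events. Passing the recovery and calibration checks
therefore demonstrates that the implementation is faithful to the model and
numerically sound — not that the model is adequate for any particular
cohort.

Benchmark conditions used by the tests and `scripts/acceptance.R`, chosen
once as a realistic desk-scale cohort: $N = 300$ samples, $k = 4$ factors,
feature counts (500, 60, 40) for expression/copy-number/protein blocks,
sparsity (0.2, 0.5, 0.5), coefficient scale $\tau = 1$, signal-to-noise 3:1,
five replicate seeds; enrichment calibration at 1000 genes, 50 sets,
`n_perm = 200`; transfer at $N = 200$ with an expression-dominated design.

The convergence benchmark (`convergence_benchmark()`) compares the rescaled
coordinate-descent arm against an arm without factor rescaling that updates
coefficients by a one-shot ridge solve plus soft-thresholding. Both arms
start from the same unit-norm principal axes — the conventional
integrative-clustering initialization that carries directions but not
scale — because starting both at the fully scaled PCA optimum would leave
nothing to converge to. The rescaled arm absorbs the scale in its first
E-step; under a nonzero penalty the non-rescaled arm's coefficients shrink
while its factors must inflate through the slow EM path, and it typically
never reaches the PCA-attainable explained variance inside the 50-iteration
horizon.

## Numerical choices and degenerate inputs

- $\Psi$ floored at $10^{-8}$; $\lambda_2$ floored at $10^{-6}$.
- The posterior precision $I + B\Psi^{-1}B^\top$ is inverted by a symmetric
  (Cholesky) solve; failure is surfaced as an error, never silently ridged.
- A factor whose coefficients vanish entirely makes the unit-variance
  rescaling impossible; `e_step()` raises an error, and `sfa_grid_search()`
  records the grid point as failed.
- PCA component signs follow the largest-magnitude-loading-positive rule;
  gene-ranking ties break by gene id; MAD-selection ties break by column
  order; exact BIC ties break toward the sparser model.
- `match_factors()` aligns factorizations up to sign and permutation by
  maximizing total absolute Pearson correlation with an exact assignment
  (exhaustive for $k \le 7$, branch-and-bound above; greedy available for
  comparison). All cross-run factor comparisons are made through it, since
  the model is identifiable only up to factor sign and order.

## Known limitations

No missing-data mechanism; Gaussian likelihood only (copy-number calls and
mutation indicators enter as continuous values or post-hoc labels); $k$ is a
user choice, not selected; no rotation post-processing; the pooled-FDR
caveat above; and the usual caveat that factor *meaning* still requires
manual inspection of coefficients and enrichments.
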