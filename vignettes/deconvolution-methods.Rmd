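---
title: "Methods: transform-then-deconvolve estimation of cell-type proportions"
author: "squidr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transform-then-deconvolve estimation of cell-type proportions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The estimation problem

A bulk RNA-seq profile $z \in \mathbb{R}^G$ of a mixed sample is modeled as
a proportion-weighted sum of cell-type expression profiles
$X \in \mathbb{R}^{G \times K}$:

$$\hat p \;=\; \arg\min_{p} \sum_g \Big( z_g - \sum_j p_j\, x_{gj} \Big)^2 ,$$

optionally subject to $p \ge 0$. When $X$ is derived from scnRNA-seq cluster
means of the *same* samples (concurrent profiling), the dominant error
source is not sampling noise but systematic measurement bias: single-cell
platforms capture transcripts with gene-dependent efficiency, and cells of
different types contribute unequal library sizes, so $X$ lives in a
different measurement space than $z$. Least squares then estimates a
distorted composition. The package's core method addresses this by mapping
$z$ into the single-cell space before solving.

# The per-gene transform

For each gene $g$ with nonzero total expression in both the bulk matrix and
the single-cell counts, the transform regresses the concurrent pseudobulk
profile $\hat z_{g,i}$ (per sample $i$: the mean expression over that
sample's cells) on the bulk profile $z_{g,i}$ across samples:

$$\arg\min_{a_g, b_g} \sum_i \big( \hat z_{g,i} - (a_g z_{g,i} + b_g) \big)^2 ,$$

solved in closed form ($a_g = \mathrm{cov}(z_g, \hat z_g)/\mathrm{var}(z_g)$,
$b_g = \overline{\hat z}_g - a_g \bar z_g$). Genes with zero bulk variance
fall back to $a_g = 0$, $b_g = \overline{\hat z}_g$ (the best constant
predictor). The transformed profile $a_g z_{g,i} + b_g$ may contain
negatives; they are kept, since the downstream solver's weights derive from
predicted reference expression, not from the transformed values.

If the per-platform distortion is an exactly per-gene multiplicative factor,
this map removes it exactly; this limit is exercised by the test suite with
the generator's `contentScalars = 1` configuration. Per-cell-*type*
distortions (library-size differences between types) are not exactly
per-gene-linear, but because the pseudobulk target is itself the
cell-fraction-weighted mean of the biased cells, deconvolving the
transformed bulk against the equally-biased cluster reference is
approximately consistent for the *cell fractions* — which is what makes the
transform effective precisely where plain least squares is most distorted.

An alternative standardizing map ("eq3" mode) matches per-gene means and
standard deviations of the two spaces,
$\vec z_{g,i} = \overline{\hat z}_g + (\hat\sigma_g / \sigma_g)(z_{g,i} - \bar z_g)$,
and does not require sample-level concurrence; genes with zero bulk standard
deviation are excluded at fit time. On the default synthetic conditions the
two modes perform equivalently (tested as an absolute RMSE difference below
0.02).

# Dampened weighted least squares

The deconvolution itself is iteratively reweighted non-negative least
squares. Starting from the plain NNLS solution $p^{(0)}$:

1. per-gene weights $w_g = 1 / \max\big((X p^{(l-1)})_g^2,\ \delta\big)$,
   with floor $\delta = 10^{-12} \max_g (Xp)_g^2$ against zero predictions;
2. weights are capped at $d \cdot \min_g \{w_g : w_g > 0\}$. The damping
   constant $d$ is selected once — from the initial solution's weights — over
   the grid $2^0 \ldots 2^{14}$, choosing the $d$ whose weighted solution has
   the smallest variance across 20 fixed-seed half-gene subsamples (a
   cross-validation variance criterion). Capping bounds the dynamic range of
   the weights, which would otherwise let near-zero-expression genes dominate;
3. the weighted NNLS problem is solved and the solution renormalized to sum
   one;
4. iteration stops when $\lVert p^{(l)} - p^{(l-1)} \rVert_2 \le \varepsilon$
   (default $\varepsilon = 0.01$, read as an absolute Euclidean bound on the
   normalized proportion vector; configurable) or after 1000 iterations,
   with a warning on non-convergence. Iteration counts and per-step norms
   are returned.

Each weighted NNLS solve reduces the $G \times K$ problem to a $K \times K$
one through the normal equations ($\lVert W^{1/2}(z - Xp)\rVert^2 =
\lVert Rp - d\rVert^2 + \text{const}$ with $R^\top R = X^\top W X$) before
applying the Lawson–Hanson active-set algorithm, so the damping search and
the iteration are cheap even with thousands of genes. If the normal
equations are numerically singular the full-size problem is solved directly.

The method uses **all genes nonzero in both the transformed bulk column and
the reference row sums** — no marker/signature selection. Reported
proportions follow convention C1 (negatives clamped to zero, renormalized to
sum one); the raw solver output is always returned alongside so either
convention can be evaluated. Reported proportions are invariant to positive
rescaling of the bulk column.

## Baseline solvers

- **OLS**: exact unconstrained least squares via QR; errors on
  rank-deficient references, naming the most collinear cluster pair.
- **NNLS**: Lawson–Hanson on the reduced system (deterministic; the entering
  rule is the standard maximum-gradient choice).
- **RLR**: Huber M-estimation (tuning constant 1.345, IRLS tolerance 1e-8)
  via `MASS::rlm`; when the least-squares fit is already numerically exact
  (zero residual scale, where the Huber estimate coincides with least
  squares) the OLS solution is returned directly, and an all-zero bulk
  vector returns a zero raw solution with undefined proportions.

## Leave-one-out cross-validation

With concurrent profiles for every sample, `looCrossValidate` predicts each
sample's composition from a transform model, cluster reference and
pseudobulk built **only** from the other samples' data. The held-out
sample's single-cell data are never read by its own fold — enforced by
construction and tested with sentinel genes and held-out-data corruption.
Folds need at least two training samples (the per-gene regression is
undefined on one point).

# Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `SolverSpec@epsilon` | 0.01 | convergence bound on $\lVert \Delta p \rVert_2$ (absolute, per sample) |
| `SolverSpec@maxIterations` | 1000 | iteration cap, warning on hit |
| `SolverSpec@dampingGrid` | $2^{0..14}$ | damping constants searched |
| `SolverSpec@nSubsamples` | 20 | half-gene subsamples in the damping search |
| `SolverSpec@seed` | 1 | seeds the damping-search subsampling (restores the caller's RNG) |
| `qcFilterCells(tail=)` | 0.005 | mass removed per side per covariate (top/bottom 0.5%) |
| `filterDetectableGenes` | 10 cells / 1% | a gene is kept iff expressed in ≥10 cells **or** ≥1% of cells of some cluster |
| `findMarkers(lfcThreshold=)` | $\log_2 1.5$ | fold-change gate on (mean+1)/(mean+1) ratios |
| `findMarkers(alpha=)` | 0.05 | BH-adjusted Wilcoxon cutoff |
| `mergeSimilarClusters(rMin=)` | 0.95 | Pearson threshold for merging cluster profiles |
| `PlatformBiasModel@tau` | 0.5 | sdlog of the per-gene and per-type capture factors |
| `PlatformBiasModel@bulkNoiseSdlog` | 0.1 | multiplicative log-normal bulk noise |
| `generateConcurrent(cellsPerSample=)` | 2000 | cells simulated per sample |
| `sampleDesign(nGenes=)` | 2000 | simulated gene universe |

# Numerical and design choices

- **QC ties.** The tail cut removes only cells strictly beyond the
  type-7 quantiles, so a constant covariate removes nothing. Mito/ribo
  fractions, when absent, are computed from configurable gene-name prefixes
  ("MT-"/"mt-"; "RPS"/"RPL").
- **Detectable genes.** The two arms are a logical OR, evaluated per
  cluster; expression means count > 0.
- **TMM.** Scaling factors come from `edgeR::calcNormFactors` (trim
  fractions 0.30 on M and 0.05 on A, reference column by upper-quartile
  proximity — the canonical parameterization); output is CPM divided by the
  factor. TPM requires a user-supplied gene-length vector.
- **Marker fold-change** uses pseudocount 1 on TMM-scale means; clusters
  with fewer than 3 cells are excluded from marker calling with a warning.
- **Merging** selects, per pass, a greedy maximal set of non-overlapping
  pairs in descending correlation (exact ties broken lexicographically by
  cluster id), merges each into a cell-count-weighted mean with summed
  counts, recomputes, and repeats; it terminates in at most (initial
  clusters − 1) passes and conserves total cell count. An auditable merge
  log (iteration, pair, r, new id) is returned.
- **Gene universes.** The transform fit uses dataset-wide nonzero totals in
  both spaces; the per-column solve uses genes nonzero in that transformed
  column and in the reference row sums. Both choices are deliberate: fitting
  wants all informative samples, solving wants the genes that constrain the
  column at hand.
- **Pseudobulk** is per sample (mean over that sample's cells), because the
  leave-one-out protocol requires per-sample pseudobulk columns; a single
  pooled pseudobulk would make the per-gene regression degenerate.
- **Single-sample datasets** cannot fit the regression mode; callers should
  use the standardizing mode, which pools across whatever bulk profiles are
  available.
- **Degenerate inputs** fail loudly with named offenders: duplicate ids,
  non-numeric cells (with coordinates), dimension mismatches in MTX
  triplets, zero column sums under normalization, empty gene universes,
  rank-deficient references, fewer shared genes than cell types.

# The synthetic generator

`sampleDesign` draws six mixtures over six types — three tumor lines, two
immune types jointly fixed at 15% of every mixture, and a stem component
cycling 0.5% / 1% / 2% (mixtures 1 and 4 at 0.5%, 3 and 6 at 2%). Mixture 1
is dominated by one tumor line (≥ 66% of the mixture), mixture 4 is
balanced, and the remaining mixtures draw the tumor trio from a Dirichlet
on the mass above a 5% per-line floor, so every line is visibly present in
every mixture — mirroring a design in which each line is a deliberate,
countable ingredient. Everything is deterministic per seed.

`generateConcurrent` then simulates, per cell type, a log-normal
(meanlog 0, sdlog 1) mean profile with a disjoint 5% block of type-specific
marker genes boosted 8-fold; bulk counts as Poisson around the depth-scaled
unbiased mixture with multiplicative log-normal noise; and single-cell
counts as negative binomial (dispersion 0.5) around capture-biased type
means, with cells assigned multinomially (a sample drawing zero cells of
some type is resampled once, then errors). The realized cell fractions are
returned as the gold standard, and the true profiles for oracle
deconvolution.

The **bias model** applies, to the single-cell side only: a per-gene
log-normal capture factor (sdlog `tau`) *and* a per-cell-type
capture/RNA-content scalar (sdlog `tau` unless supplied explicitly) —
the latter because cell types differ strongly in size and per-cell UMI
yield, which rescales whole reference columns and is the dominant reason
proportion estimates from untransformed bulk are distorted. A purely
per-gene, type-shared factor, by contrast, largely cancels in renormalized
least squares when type profiles are exchangeable, and would make the
platform-bias problem look artificially benign. `tau = 0` gives an exactly
unbiased platform. Optional switches: mean-dependent dropout thinning
(per-gene, hence linearity-preserving; off by default so that `tau` is the
single bias dial) and a per-(gene, type) capture factor
(`typeDependentBias`) that deliberately violates the transform's
per-gene-linearity assumption, for probing the method's failure mode.

`expectedValueMode` emits exact expectations instead of sampled counts
(deterministic cells equal to the biased type means, the exact pseudobulk
expectation, gold standard equal to the design), enabling machine-precision
solver tests.

**What the generator does and does not emulate.** It reproduces the
mixture geometry, cross-platform capture structure, count noise and
per-sample concurrence of a real mixture experiment. It does not emulate
ambient RNA, doublets, batch effects between samples, preservation-protocol
type depletion beyond the content scalars, gene–gene correlation within
types, or realistic gene-length structure (so TPM on synthetic data is only
exercised mechanically). Passing tests on these data therefore demonstrate
correctness of the estimators under the stated model, not performance on
any particular real tissue.

# Problem sizes

The test suite and the acceptance script run at the design's native scale —
6 samples × 6 types × 2000 genes × 2000 cells/sample — for the headline
checks (20 replicate datasets for the SQUID-vs-DWLS ordering; 10 in the
acceptance script), and at a reduced scale (300–500 genes, 1500
cells/sample) for module-level property tests such as the bias-monotonicity
sweep, where the properties under test are scale-free. Sizes are stated in
the tests themselves.

# Known limitations

- The transform is per-gene linear; platform distortions that mix genes or
  act nonlinearly (saturation, strong mean-dependent dropout) are only
  partially corrected, and `typeDependentBias = TRUE` demonstrates the
  degradation.
- The regression mode needs several concurrent samples (≥ 3 for
  leave-one-out; precision grows with sample count — with 6 samples the
  per-gene slopes are estimated from 5 points).
- Estimates are RNA-proportion-based; without the transform they conflate
  cell fractions with per-type RNA content.
- The robust and ordinary solvers report clamped-renormalized proportions;
  when all raw coefficients are non-positive there is no meaningful
  composition and the solvers error rather than guess.
- External methods (nu-SVR approaches, Bayesian mixture models) are not
  reimplemented; the benchmark grid accepts their composition tables as
  files instead.
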