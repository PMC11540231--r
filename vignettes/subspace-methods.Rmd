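---
title: "Subspace methods for few-shot image classification: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subspace methods for few-shot image classification: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fewsubspace)
```

## Setting

`fewsubspace` targets the regime where a frozen deep network maps each
image to an M-dimensional feature vector (M ≈ 512 for a typical
penultimate layer) and only a few hundred labelled images exist. With
N ≲ M, distance-based classifiers degrade and the within-class scatter
matrix is singular, so dimensionality reduction is not an optimization but
a prerequisite. The package provides three families of subspaces —
principal-component (SVD), discriminant, and non-negative — together with
the episode-based evaluation protocol that measures them.

The statistical assumption underlying the discriminant machinery is that
class-conditional feature distributions are unimodal with comparable
within-class covariance, so that first- and second-moment summaries
(class means and scatter matrices) capture the separability. PCA assumes
additionally that variance indicates relevance — the assumption the
variance-trap generator is designed to violate.

## Scatter statistics

For samples $y_i \in \mathbb{R}^M$ in classes $\Lambda_j$ of sizes $N_j$,
with class means $\bar y_j$ and global mean $\bar y$:

$$S_{Wj} = \sum_{k=1}^{N_j} (y_k^j - \bar y_j)(y_k^j - \bar y_j)^\top,
\qquad S_W = \sum_j S_{Wj}, \qquad
S_B = \sum_j (\bar y_j - \bar y)(\bar y_j - \bar y)^\top.$$

Note $S_B$ sums one **unweighted** rank-one term per class, so
$\mathrm{rank}(S_B) \le C-1$; this is the form the discriminant
eigenproblem below consumes. (The classical total-scatter decomposition
$S_T = S_W + \sum_j N_j(\bar y_j - \bar y)(\bar y_j - \bar y)^\top$ uses
the size-weighted between-class scatter; the test suite checks that
weighted identity.)

For two classes the package additionally forms $s_b = \bar y_1 - \bar y_2$,
$\tilde S_B = s_b s_b^\top$ and the pooled
$\tilde S_W = \beta S_{W1} + (1-\beta) S_{W2}$ with
$\beta = (N_2 - 1)/(N_1 + N_2 - 2)$ — the unbiased pooled-covariance
weighting, up to overall scale. Class 1 is whichever class appears first
in the label column: class order is positional throughout the package, so
results are deterministic without assuming label semantics.

Inputs are validated for finiteness up front: scatter accumulation would
silently absorb NaN otherwise. Feature width is capped (default 4096, see
option `fewsubspace.max_features`) to keep the dense M×M allocations an
explicit decision.

## Discriminant subspaces

**Multiclass.** `fit_multiclass_da()` solves
$S_B d = \lambda (S_W + \delta I) d$ and keeps the top $C-1$ (or fewer)
eigenvectors. The ridge $\delta$ (default $5\times10^{-3}$, dimensionless
in feature-variance units) exists because $S_W$ is exactly singular when
$N < M$ and near-singular well before that. Numerically the solver never
forms $(S_W+\delta I)^{-1} S_B$: it Cholesky-factorizes
$S_W + \delta I = R^\top R$, symmetric-eigensolves
$R^{-\top} S_B R^{-1}$, and back-transforms — mathematically identical,
numerically stable. Two bases are kept: the raw generalized eigenvectors
(`$eigvecs`, which satisfy the eigen identity but are not mutually
orthogonal) and their re-orthonormalized span (`$basis`) used for
projection.

**Binary (Foley–Sammon).** For $C=2$ the Fisher criterion
$R(d) = (d^\top \tilde S_B d)/(d^\top \tilde S_W d)$ yields one direction;
`fit_foley_sammon()` extends it to an orthogonal sequence: $d_1 = \alpha_1
\tilde S_W^{-1} s_b$, and

$$d_n = \alpha_n \tilde S_W^{-1}\Big(s_b - [d_1 \cdots d_{n-1}]\,
S_{n-1}^{-1}\, e_1/\alpha_1\Big), \qquad
(S_{n-1})_{ij} = d_i^\top \tilde S_W^{-1} d_j,$$

each $d_n$ maximizing $R$ subject to orthogonality with all previous
directions, up to $L \le M$ directions. Each direction's attained ratio is
its *discrim-value* $\gamma_n$, and $\gamma_1 \ge \gamma_2 \ge \dots \ge 0$
orders the basis the way singular values order an SVD basis.

Numerical choices worth knowing:

* $\tilde S_W^{-1}$ is applied through a cached Cholesky factorization;
  the Gram matrix $S_{n-1}$ is grown incrementally and solved directly,
  with failure reported at the first unrecoverable step.
* In exact arithmetic the recursion produces orthogonal directions; in
  floating point the error compounds geometrically as the discrim-values
  decay. Each new direction therefore gets two Gram–Schmidt sweeps against
  its predecessors — a no-op in exact arithmetic that keeps
  $\max|D^\top D - I|$ at the 1e-15 level instead of 1e-4 by L = 10.
* Ridge policy: the multiclass $\delta$ applies always (it must be
  positive). For the binary scatter the ridge engages automatically when
  $N \le M$ or the condition estimate of $\tilde S_W$ exceeds 1e12, with
  the same default $5\times10^{-3}$; an explicit `delta` overrides in
  either direction. Rationale: the few-shot regime makes $\tilde S_W$
  singular in exactly the way the multiclass ridge anticipates.
* When a ridge was used, the discrim-value denominator uses the
  regularized $\tilde S_W + \delta I$ by default — consistent with the
  quantity the fit actually maximized — and the raw-denominator value is
  reported alongside (`discrim_value_raw`) since the definition is
  ambiguous under regularization.
* Sign convention: every basis column has its largest-magnitude entry
  positive (ties: lowest index). $d_1$ keeps the sign its positive
  normalizing constant induces; flipping later directions does not affect
  the recursion. This makes fits bit-reproducible.
* Degenerate inputs error loudly rather than truncate: requesting more
  directions than $M$, coincident class means ($s_b = 0$, every ratio
  zero, the recursion undefined), or a singular Gram step all name the
  failure.

**PCA.** `fit_pca()` centers with the *training* mean and takes top-p
right singular vectors. Whether the SVD baseline should center is a
genuinely open choice (centered PCA is the natural reading of
"principal components"; raw SVD is also used in practice), so both are
available via `center = TRUE/FALSE`, with centering the default. Test data
are always centered with the training mean — never their own — to avoid
leakage.

## Non-negative factorizations

`fit_nmf()` minimizes $\|Y - KX\|_F^2$ over $K \in \mathbb{R}^{N\times p}_{\ge 0}$,
$X \in \mathbb{R}^{p\times M}_{\ge 0}$ with the classic multiplicative updates

$$K \leftarrow K \odot \frac{Y X^\top}{K X X^\top}, \qquad
X \leftarrow X \odot \frac{K^\top Y}{K^\top K X}.$$

Choices and rationale:

* Denominators get a pointwise $\varepsilon = 10^{-12}$; zero rows or
  columns then flow through as zeros instead of NaN, and the monotone
  decrease of the objective survives to a 1e-9 relative tolerance.
* Initialization draws entries uniformly from (0, 1] scaled by
  $\sqrt{\bar Y / p}$ so that $KX$ starts on the data's magnitude —
  a scale-matched start stabilizes the first iterations. Everything is a
  pure function of the seed.
* The default 3000 iterations are run in full, no early stopping; the
  iteration at which relative improvement first drops below 1e-9 is
  recorded as a diagnostic (`converged_at`).
* Negative inputs are clipped at zero with a message (post-ReLU deep
  features are non-negative, so clipping is normally a no-op);
  `strict = TRUE` turns this into an error.
* Out-of-sample rows get coefficients by running the K-update with X
  frozen (constant positive start, stop at relative change 1e-8 or 500
  sweeps). This matches the training objective and code path; the test
  suite cross-checks it against a non-negative least-squares oracle.

**Supervised NMF** (`fit_snmf()`, binary only) couples the labels in by
jointly factorizing the features and a one-hot label matrix
$Z \in \{0,1\}^{N\times 2}$:

$$\min_{K,X,B \ge 0} \|Y - KX\|_F^2 + w\,\|Z - KB\|_F^2,$$

with the K-update blending both terms and X, B keeping their standard
updates. This is the standard way the supervised-NMF literature injects a
classification cost into the factorization, and it has the property that
anchors the implementation's correctness: at $w = 0$ the K and X
trajectories are **bit-identical** to plain NMF from the same seed
(K and X are initialized first, in the same RNG order). The coupling
weight trades reconstruction against label fit and is data-scale
dependent; it has no defensible universal default, so the argument is
required. Multiclass SNMF is out of scope.

## The evaluation protocol

`evaluate_pipeline()` runs, for repeat $r = 1..R$ (default $R = 10$):
draw a per-class episode (seed `master_seed + r`; e.g. an 8-class problem
at 75/25 per class gives 600 train, 200 test rows), fit the configured
subspace **on the training episode only**, project both splits, and score
KNN at every $K \in \{1, 5, 10, 15\}$. The per-repeat summary is the mean
over $K$ first; the reported mean ± sd (unbiased, $n-1$) is then taken
across repeats. Whether a reported spread should also pool K-level
variation is ambiguous, so the report stores both conventions
(`sd_accuracy`, `sd_accuracy_pooled`) and the full per-repeat per-K table.

KNN ties are broken deterministically: equidistant neighbours by training
row index (stable ordering), tied majority votes by the nearest neighbour
belonging to a tied class, then lowest class index. Distances are
accumulated in double precision with a fixed reduction order so near-ties
reproduce across runs. The SVM arm wraps `e1071::svm` (radial kernel,
fixed seed, no scaling) for comparison; its hyperparameters come from the
caller.

`z_test_accuracy()` compares two arms with a two-sided two-sample Z on the
per-repeat accuracies, standard error $\sqrt{s_a^2/n_a + s_b^2/n_b}$. The
exact form of such a test is a convention; this one matches the
repeat-sampling structure that produced the numbers. Two constant equal
arms give $z = 0$, $p = 1$ by convention rather than an error.

Default dimensions follow the protocol: $C-1$ for multiclass DA (the rank
bound of $S_B$), 30 for PCA/NMF/SNMF, and the full feature space for the
no-reduction arm.

## What the generators emulate — and what they do not

`generate_mixture()` emulates penultimate-layer deep features as
class-conditional Gaussians with per-coordinate scales drawn once per spec
from a long-tailed log-normal (sdlog 0.75), optionally rectified at zero
to mimic post-ReLU statistics. Real deep features also carry correlated
coordinates, heavier tails, and within-class multi-modality that this
generator does not reproduce; a test passing on these mixtures shows the
algebra and protocol are right, not that any particular accuracy level
transfers to real images.

`generate_variance_trap()` is the designated adversarial surface for the
central claim that discriminant subspaces beat variance-preserving ones at
low dimension: the class signal (mean gap 2, within-class sd 0.5, total
variance 1.25) lives only in the last coordinate while nine nuisance
coordinates carry class-independent variance 25. The leading principal
component is then near-orthogonal to the discriminant direction by
construction, and the generator refuses specs where the trap would not
hold. These defaults are a sharp, intentionally favourable illustration —
real data degrade PCA gradually, not categorically.

`generate_planted_nmf()` plants $Y = K^* X^*$ with sparse non-negative
factors (entries in (0.2, 1], default 30% zeroed, no all-zero row or
column so the planted rank is genuine) plus optional rectified Gaussian
noise, and returns the ground truth for recovery experiments.

All generators are pure functions of their spec, and generated tables pass
the same validation as user data.

## Problem sizes in the shipped tests

The test-suite and acceptance-script study conditions are chosen to be
desk-scale while preserving the regime of interest: random binary problems
at N = 60, M ≤ 20 for the eigensolver cross-checks (50 seeds);
a 50 × 40 matrix, rank 5, for NMF monotonicity over the full 3000
iterations (20 seeds) and a 50 × 40 planted rank-3 instance for recovery;
the variance trap at its default 2 × 60 × 10 with ten generator seeds and
ten episode repeats per arm. Feature width 512 is exercised where cheap
(generation, I/O shape checks) but the heavy linear algebra in tests runs
at M ≤ 64.

## Known limitations

* Multiclass DA yields at most $C-1$ dimensions — an intrinsic rank bound,
  limiting for problems whose structure is in covariance differences
  rather than mean differences (where any mean-based discriminant method
  underperforms).
* Foley–Sammon directions are defined for binary problems only; the
  package deliberately errors rather than silently one-vs-resting.
* Supervised NMF is binary-only, and NMF coefficients for test rows depend
  on a fixed basis whose parts were learned without those rows; nothing
  guarantees per-row optimality beyond the NNLS-level agreement the tests
  check.
* Scatter computation is dense and in-memory; there is no streaming or
  sample-weighting support.
* Feature extraction from images is a plugin contract
  (`register_extractor()` / `run_extractor()`, with per-image
  standardization and an 1e-8 guard for constant images); the package
  ships no network backend. Per-image versus per-channel normalization is
  selectable, per-image being the default.
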