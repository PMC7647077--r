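---
title: "Modulator-indexed network tensors: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modulator-indexed network tensors: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netten)
```

netten studies how gene regulatory networks change along a scalar,
per-sample biological characteristic — the *modulator*. The motivating
case is an epithelial–mesenchymal transition (EMT) score over cancer cell
lines: epithelial-like and mesenchymal-like cells wire their regulatory
programs differently, and a single network fitted to all samples averages
those differences away. This vignette describes the three models the
package implements, the parameters that matter, what the synthetic
generator does and does not emulate, and the design choices made where
the methodology was genuinely open.

## Stage 1: sample-specific networks by kernel-weighted regression

For target gene $Y_l$ and candidate regulators $X_1,\dots,X_q$ we assume
a varying-coefficient linear model: the effect of regulator $j$ on target
$l$ is a function $\beta_{jl}(m)$ of the modulator. The network of sample
$\alpha$ is estimated by localizing an elastic-net regression around
$m_\alpha$ with Gaussian kernel weights

$$w_i = \exp\{-(m_i-m_\alpha)^2/b\},$$

so samples with a similar modulator dominate the fit
(`gaussian_kernel_weights()`). Note the bandwidth $b$ divides the squared
distance directly — it has units of squared modulator, and the kernel's
standard deviation is $\sqrt{b/2}$.

`fit_target_sample()` minimizes the kernel-weighted squared error plus a
*recursive* elastic-net penalty: round 1 is a standard elastic net; each
later round refits with per-coefficient penalty weights
$1/(|\hat\beta_j|+\delta)$, so coefficients that were small are pushed to
exact zero while established edges are penalized less. Two rounds with
$\delta=10^{-4}$ are the default; one round recovers the plain elastic
net. Regulators are standardized to kernel-weighted zero mean and unit
variance inside each localized fit (penalization fairness: a regulator's
chance of selection should not depend on its scale in the
neighbourhood), and coefficients are reported back on the original
scale. A gene serving as both target and regulator is never offered as
its own regulator, so self-edges are structural zeros. The penalized
solves are delegated to glmnet; at $\lambda=0$ the exact weighted
least-squares solution is computed instead, because coordinate descent
is iterative and we promise closed-form agreement there.

An edge *exists* in sample $\alpha$'s network exactly when its fitted
coefficient is nonzero after the final round. All downstream adjacency
analysis inherits this definition.

### Choosing the bandwidth and penalty

Neither the bandwidth nor $\lambda$ has a universal default, and the
choice matters more than any other tuning in the package.
`select_hyperparameters()` scores a (bandwidth × lambda × alpha) grid by
K-fold cross-validated squared prediction error, *kernel-weighted* around
the target sample — held-out samples far from $m_\alpha$ contribute
little, so the criterion measures local fit, which is what a
sample-specific network needs. With a uniform modulator on $[-1,1]$ and
piecewise-constant coefficient functions, smaller bandwidths trade
variance for locality; on such data the CV criterion reliably selects
$b \approx 0.05$ (kernel sd $\approx 0.16$, roughly 20–25 effective
samples at $n=120$). The hand-set fallback default $b=0.2$ is deliberately
conservative (smoother estimates, more cross-regime borrowing); pass
`bandwidth = NULL` to `build_network_tensor()` to use the CV selector,
which is what the bundled end-to-end analyses do. Kernel smoothing has a
visible consequence for sharp transitions: a step edge's estimate ramps
over a window of about one kernel sd around the changepoint, so
regime-specific recovery should only be expected beyond that window (we
use $|m - \text{changepoint}| > 0.5$, about 1.5 kernel widths at the
default bandwidth, when quantifying it).

## Stage 2: supervised orthonormal subspace learning

Each sample's fitted coefficient network is a matrix
(targets × regulators); the collection is a third-order tensor. The
stage-2 learner compresses every sample network through mode-wise
projections $\bar X_i = C^{(1)T} X_i C^{(2)}$ with orthonormal
$C^{(k)} \in \mathbb R^{I_k\times J_k}$, and simultaneously predicts a
response $y_i$ (typically the modulator itself) from the projected
network. The objective is

$$\frac1n\sum_i \Big\{ L(y_i,\hat y_i) +
  \gamma\,\|X_i - C^{(1)}\bar X_i C^{(2)T}\|_F^2 \Big\},
  \qquad C^{(k)T}C^{(k)}=I,$$

so the subspace is shaped jointly by reconstruction (retain network
variance) and prediction (retain response-relevant structure). The
trade-off $\gamma$ defaults to 1 — equal weight per unit of squared
error — and is exposed; at $\gamma\to\infty$ the learned span provably
approaches the plain HOSVD subspace, a useful sanity limit that the test
suite checks. The reconstruction term is implemented as the
back-projection residual $X_i - C^{(1)}\bar X_i C^{(2)T}$; for
orthonormal projections this equals
$\|X_i\|_F^2 - \|\bar X_i\|_F^2$, which is how it is evaluated.

The prediction head reads the scalar
$r_i = \langle W, \mathrm{vec}(\bar X_i)\rangle$ and maps it through
either a one-hidden-layer tanh network of width 16 (default) or an
identity/linear map (useful for tests, and exactly solvable). Squared and
logistic losses are supported.

**Optimization.** The orthonormality constraint is enforced through the
SVD polar factor: for a latent matrix $Z^{(k)} = PSQ^T$, the closest
orthonormal matrix is $C^{(k)} = PQ^T$. Each outer iteration (i) updates
the head — in closed form for the linear/squared case, by backtracked
gradient steps otherwise; (ii) takes a gradient step on each $C^{(k)}$,
forming $Z^{(k)} = C^{(k)} - \eta\,\partial O/\partial C^{(k)}$, and
re-orthonormalizes through the polar factor; (iii) backtracks $\eta$
until the objective does not increase. The objective history is therefore
monotone non-increasing by construction, and the orthonormality deviation
stays at SVD roundoff ($<10^{-12}$ in practice; the guarantee tested is
$10^{-8}$). Projections are initialized at the HOSVD of the mean-centred
slices — the reconstruction optimum — so prediction-driven refinement
starts from an interpretable basis. Convergence is declared at a relative
objective change below `tol` ($10^{-6}$) or `max_iter` (500). All
stochastic initialization flows through the single `trip_control(seed=)`.

### Choosing the subspace dimensions

$J_k$ must be large enough to hold every regulatory *program* whose
variation matters: the shared backbone of stable edges occupies one
direction per mode, and each modulator-dependent program adds another.
In the bundled marker study (3 modulator-driven regulators over a
constant backbone) mode-2 needs at least 4 directions; we use
$J=(5,5)$. When $J_2$ is too small the backbone and the varying programs
collide in the projected space; the symptom is that the *raw* per-sample
vectors still track the response while the normalized ones do not. At
desk scale this is cheap to over-provision; on large tensors the choice
mirrors the usual scree inspection of `variance_explained`.

## Interpretation: surrogate, components, markers, REC

**Multi-linear surrogate.** The head is made attributable by
approximating it with a rank-one bilinear read-out
$\hat y_i' = g^{(1)T}\bar X_i\, g^{(2)} + b$, fitted to the head's own
predictions by alternating least squares (each factor sub-problem is an
ordinary regression). Factor norms are balanced after every sweep
(the rank-one parametrization is scale-indeterminate), and for a linear
head the factors are initialized at the rank-one truncation of the
head's actual read-out matrix, which is exact when that matrix is rank
one. The reported `fit_gap` quantifies how much of the head the
surrogate explains.

**Crucial components.** Per sample,
$u_i^{(2)} = C^{(2)T} X_i^T C^{(1)} g^{(1)}$ contracts the non-analyzed
mode with its projection and surrogate factor; stacking the unit-
normalized $u_i$ and running PCA over samples yields components of
network variation that matter for prediction. Normalization is unit
L2 per column (all-zero vectors are kept as zero columns to preserve
sample alignment); PCA mean-centres samples; component signs are fixed
by making the largest-magnitude loading positive, and components are
ordered by decreasing variance. On smoothly modulated networks with a
shared backbone the first component's scores track the modulator almost
perfectly — the package's analogue of observing that the leading
component "rediscovers" the EMT axis. Two geometric caveats are worth
recording: normalization discards magnitude, so a fixture whose only
variation is a single zero-mean direction collapses to a sign pattern
(correlation caps near 0.87); and strictly orthogonal planted factor
pairs are annihilated by the surrogate contraction. Real coefficient
networks — and the bundled study generators — have a shared backbone on
the same targets, which is exactly what makes the normalized vectors
trace a smooth curve in the modulator.

**Differential markers.** Sample regions are compared through binary
adjacency: edge present in a region iff nonzero in at least one of its
samples. The one-sample union rule is deliberately strict (it is the
region's edge *repertoire*), which has two practical consequences:
regions should be taken from the extremes of the component being
analyzed (`split_samples(mode = "top_bottom_N")` with N around 13% of
samples per side, mirroring 100-of-762 in the motivating study), and
region sizes should not be so large that they reach into the kernel
ramp around a transition, where smoothed coefficients are legitimately
nonzero on both sides. Genes are scored by the number of incident
differing edges between the two regions' adjacency matrices (row plus
column of $|A_{high}-A_{low}|$, diagonal excluded; a row-only variant is
available), and the top-k by score are the markers. All orderings break
ties by ascending gene/sample ID, so results are reproducible to the
byte.

**RE and REC.** The realized strength of an edge in sample $\alpha$ is
$RE_{jl\alpha} = \hat\beta_{jl}(m_\alpha)\,x_{\alpha j}$, and its
modulator dependence is summarized by the range
$REC_{jl} = \max_\alpha RE - \min_\alpha RE$ — zero exactly for edges
absent everywhere, nonnegative by construction. Column-centred PCA of
the REC matrix restricted to the marker columns gives the biplot in
which markers with similar modulator-dependent regulation group
together. Mean-RE summaries over a sample set optionally drop edges
whose mean is exactly zero (they cancel, carrying no net effect at that
end of the modulator). Tissue association of a region split is tested by
the plain Pearson chi-squared on the 2×2 membership table, without
continuity correction (a flag restores Yates), flagged at 0.01, 0.001
and 0.0001.

## The synthetic generators

`generate_dataset()` realizes the varying-coefficient model directly:
regulators i.i.d. standard normal (matching the standardized-expression
convention and making oracle algebra exact), coefficient functions from
a small vocabulary — `constant`, `step`, `sigmoid`, `zero` — and i.i.d.
Gaussian noise. The modulator defaults to uniform on $[-1,1]$, which is
the regime the motivating application reports. `generate_network_tensor()`
bypasses stage 1 and plants orthonormal rank-$R$ factors with per-sample
scores, for direct stage-2 testing; scores of factor 1 are uniform
(modulator-like) and higher factors carry a constant offset (1.5) plus
N(0, 0.3) variation — the shared-backbone structure discussed above.
Two study-level fixtures wrap these: `simulate_study()` (three designated
step-profile regulators, 8 target edges each of height 2, over a
constant or mixed backbone at roughly 60/20/10/10
zero/constant/step/sigmoid edges; expression noise sd 0.1) and
`simulate_smooth_study()` (gentle sigmoid variation over a constant
backbone). Sizes used throughout the tests — $n$ of 100–200, tens of
genes — are chosen so every stage runs in seconds while keeping the
estimation problems honestly noisy.

What the generators do *not* emulate: realistic expression marginals
(log-normal skew, zero inflation), correlated regulators, miRNA-specific
repression, copy-number confounding, or measurement batch structure.
Passing tests demonstrate that the estimators recover the structures the
model class describes under Gaussian noise; they say nothing about
robustness to mis-specified marginals, which on real data should be
addressed by the usual preprocessing upstream of this package.

## Numerical conventions and degenerate inputs

* Ties everywhere break by ascending ID; duplicated hyperparameter grid
  points resolve to the first occurrence.
* Constant regulators inside a kernel neighbourhood (weighted variance
  ≈ 0) are excluded from that fit and reported as exact zeros.
* `orthonormalize()` refuses rank-deficient input and names how many
  directions collapse; the optimizer's line search treats that as a
  rejected step.
* A constant score vector under a median split warns and assigns all
  samples to the low region.
* An all-zero weight vector is a degenerate fit and errors; an all-zero
  projected tensor in the surrogate returns the mean prediction with
  normalized default factors.
* Every generator takes an explicit seed and restores the caller's RNG
  state; the pipeline's manifest records config and output checksums so
  a run is reproducible byte for byte.

## Known limitations

Second-order (matrix) sample tensors only — $K>2$ modes are out of
scope. The MLP head is intentionally small and CPU-bound; there is no
mini-batching. The stage-1 loop fits each (target, sample) pair
independently and scales as $I_1 \times n$ penalized regressions;
practical desk-scale limits are a few thousand such fits per minute.
Hyperparameter selection optimizes local predictive error, not edge
recovery directly; when edge-set fidelity is the goal, the bandwidth
grid should extend low enough for the CV criterion to express its
preference for locality.
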