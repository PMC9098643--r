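---
title: "Reconstructing consensus 3D chromosome structures by low-rank distance-matrix completion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing consensus 3D chromosome structures by low-rank distance-matrix completion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoscaffold)
```

## The model

A chromosome is treated as a beads-on-a-string polymer: bin $i$ of a fixed
width (say 5 kb) occupies a point $p_i \in \mathbb{R}^3$, collected in the
$N \times 3$ coordinate matrix $P$. Hi-C measures, after Knight–Ruiz
balancing, an interaction frequency $IF_{ij}$ for a subset of bin pairs;
the package converts it to an observed squared spatial distance by the
power law

$$D_{ij} = IF_{ij}^{-\eta}, \qquad \eta = 0.5 \text{ by default},$$

and treats zero-contact pairs as *missing*, not infinitely far: they simply
stay outside the measurement set $\Omega$.

The central object is the Gram matrix $X = PP^\top$ of the centered
coordinates. It has rank $\le 3$, and the squared Euclidean distance matrix

$$D = \mathrm{diag}(X)\mathbf{1}^\top + \mathbf{1}\,\mathrm{diag}(X)^\top - 2X$$

has rank $\le 5$ (a rank-$\le 3$ term plus two rank-1 terms). With only
$\sim 5N$ intrinsic degrees of freedom in an $N \times N$ matrix, a modest
random subset of measured pairs suffices to pin down the whole geometry —
this is what makes reconstruction from sparse, high-resolution Hi-C
feasible, and it is the property the solver exploits.

## The solver

Measurements enter through a sampling operator: for the pair list
$\alpha_k = (a, b)$,

$$A(X)_k = X_{aa} + X_{bb} - 2X_{ab},$$

i.e. the squared distance implied by $X$; its adjoint $A^*$ scatters a
vector back into the corresponding sparse symmetric pattern. Neither is
ever materialized densely (`src/solver_kernels.cpp`). The sub-diagonal
operator $B$ is the same construction on pairs $(i, i+1)$.

The structure minimizes the trace surrogate of rank subject to matching
the measured squared distances $b = A(M)$, with a penalty keeping adjacent
bins at a realistic spacing $d^t$. The augmented Lagrangian is

$$L(P; \Lambda) = \mathrm{Tr}(PP^\top)
  + \tfrac{\lambda}{2}\,\lVert B(PP^\top) - d^t\mathbf{1}\rVert^2
  + \tfrac{r}{2}\,\lVert A(PP^\top) - b + \Lambda\rVert^2,$$

with gradient
$2P + 2\lambda B^*(B(PP^\top) - d^t\mathbf{1})P + 2r A^*(A(PP^\top) - b + \Lambda)P$.
Defaults $\lambda = 10$, $r = 1$; accuracy is insensitive to both. The
adjacent-distance penalty is symmetric about $d^t$ (deviations in either
direction are penalized), which is the form whose gradient is printed
above.

Each outer iteration runs up to 20 Barzilai–Borwein steps on $P$
(alternating BB1/BB2 step sizes, clamped to $[10^{-12}, 10^{12}]$, with a
monotone Armijo backtracking safeguard so accepted steps never increase
$L$), then updates the multiplier, $\Lambda \leftarrow \Lambda + (A(PP^\top) - b)$.
Iterations stop when the mean relative absolute error between
$\sqrt{A(PP^\top)}$ and $\sqrt{b}$ over $\Omega$ falls below `tol`
(default $10^{-3}$; the convergence norm had to be chosen here, and a
relative error is used so the criterion is scale-free).

Three numerical choices deserve explanation:

* **Initialization.** $P$ starts from i.i.d. normal entries with variance
  $d^t/6$, so initial adjacent distances already match the scale the
  penalty enforces. `d_t` is in *squared*-distance units (it is compared
  against $B(X)$, which returns squared distances); when unset it defaults
  to the median measured adjacent squared distance, and `tune_dt()` offers
  the grid search that picks the candidate with the smallest penalized
  objective (ties toward the smaller value). The tuning grid is log-spaced
  around that median — an implementation choice, since no canonical grid
  exists.
* **Early stopping (`stall_window`, `stall_rel`).** On noisy inputs the
  constraints are not exactly satisfiable by a rank-3 Gram matrix, so the
  measured error plateaus above `tol` while the multipliers keep pushing
  the iterate toward *interpolating the noise* — the classic
  semi-convergence of iterative inversion. The solver therefore stops once
  the measured-set error has not improved by `stall_rel` (0.5%) for
  `stall_window` (5) consecutive multiplier updates. The check arms only
  after the error has halved from its initial value, because the first few
  multiplier updates are non-monotone. Everything this rule looks at is
  observable data fit, never agreement with a ground truth.
* **Multi-start (`n_starts`).** The factorized problem is nonconvex and a
  random start occasionally lands in a visibly poor local minimum
  (markedly higher measured error). Three starts are run from derived
  seeds and the solution with the lowest measured-set error is kept; a
  start that converges below `tol` short-circuits the rest.

Coordinates are finally extracted by eigendecomposition with negative
eigenvalues clipped at zero — the closest-PSD projection in spectral
terms, needed because an ALM iterate is not exactly PSD. All randomness
derives from a single seed through named sub-streams (`derive_seed()`), so
components are independently reproducible.

## Hierarchical assembly

For long chromosomes the problem is split across two scales: a
domain-level skeleton (default 1 Mb tiles) and independent intra-domain
problems, which parallelize naturally. Three design gaps had to be closed
because only the rotation criterion is fully specified:

* **Domain-level input.** The squared distance between two domains is the
  *median* of the measured fine-scale squared distances between them —
  robust to noise. This aggregate systematically overestimates the
  center-to-center squared distance by the two domains' squared radii of
  gyration (for the mean over centered fragments this is an exact
  identity), so `reconstruct_hierarchical()` debiases the skeleton input
  with $r_g^2$ estimated from the already-solved intra-domain structures,
  flooring at 5% of the raw value for positivity.
* **Unit reconciliation.** A single global scale for the skeleton is
  estimated by least squares on the measured cross-domain pairs (a 1-D
  quartic, minimized by grid bracketing plus `optimize()`).
* **Orientation.** Each intra-domain structure, centered at its skeleton
  point, is rotated to fit the measured squared distances between
  fragments of *adjacent* domains: the discrepancy
  $(\lVert r_\theta(S_{i,j} - C_i) + C_i - S_{i+1,k}\rVert^2 - D_{i,j;i+1,k})^2$
  is summed over measured cross pairs (both sides are squared distances —
  the literal reading of the printed criterion, which is what is
  implemented). Rotations are found by coordinate-descent sweeps: domains
  left to right, axes in x, y, z order, each angle minimized on a 64-point
  grid over $[0, 2\pi)$ with golden-section refinement; a per-domain point
  inversion is also tested because distance data cannot determine
  chirality. When minimizing a domain's angle the pairs with *both*
  neighbors are counted, so each accepted move lowers the total objective
  and sweeps are provably non-increasing (`sweep_objectives` records
  this). Non-adjacent cross pairs are used for evaluation only.

Two further refinements proved necessary in practice and are part of this
package's design:

* **Landmark initialization.** Starting all domains at random orientations
  drops the coupled rotation objective into a deep spurious local minimum
  that per-axis descent cannot leave (verified on an oracle where the
  global optimum is exactly zero). The sweeps are therefore initialized
  from a coarse global reference: the flat solver is run on the
  sub-matrix of ~6 landmark bins per domain (a tiny problem), the landmark
  solution is orthogonally mapped onto the skeleton frame via its domain
  centroids, and each intra-domain structure is orthogonally fitted
  (reflections allowed) to its landmarks.
* **Center refinement.** The debiased skeleton still carries small center
  errors that rotations alone cannot absorb, so each sweep also applies a
  few damped Gauss–Newton steps to every domain center against the same
  cross-pair objective, accepted only when the objective decreases
  (`refine_centers = TRUE`).

With a trivial single-domain partition the function reduces exactly to the
flat solver.

## The integrative mode

Chromatin accessibility carries structural information: co-accessible loci
tend to sit closer in 3D. The package fits, on measured pairs of a source
dataset,

$$D_{ij} = \alpha\,(S_i + S_j) + \alpha_3 G_{ij} + c,$$

where $S$ is the per-bin mean accessibility signal and $G_{ij}$ the 1D
genomic separation in bp. Two deliberate deviations from the obvious
asymmetric, intercept-free form: the accessibility term is symmetrized
($\alpha_1 = \alpha_2$) because $D$ is symmetric, so an unsymmetrized fit
would depend on arbitrary pair ordering; and an intercept is included
(reported separately, used in imputation) because forcing the fit through
the origin visibly biases the slopes. Imputed matrices are floored at
$10^{-6}\times$ their median so they remain valid squared distances.

`solve_integrative()` adds
$\gamma\,\lVert A_E(PP^\top) - A_E(E^M)\rVert^2$ to the objective, where
$E^M = -\tfrac12 J E J$ is the double-centered Gram matrix of the imputed
matrix $E$ and $A_E$ samples the measured source pairs *plus* a uniform
sample of unmeasured pairs (at the base `k_rate`) — the imputed,
target-specific information must reach pairs the source Hi-C missed, or
the penalty would merely re-weight existing constraints. $\gamma$ defaults
to 0.5 (no canonical value exists; it is logged and tunable), and
$\gamma = 0$ reduces bit-for-bit to the base solver under the same seed.
Resolution boosting expands an $m \times m$ matrix by fragment splitting —
children inherit the parent's pairwise distances, same-parent child pairs
stay unmeasured — then refits the regression at high resolution and runs
the integrative solver.

## The simulation benchmark

`generate_benchmark()` supplies the ground truth the protocol needs, since
no reference simulated structures are published. The default `"loop"`
curve is a helix-of-helices (a minor helix winding around a circular-arc
carrier), mimicking chromatin folding at two scales; `"helix"` gives a
maximally regular chain, and `"random-walk"` a smoothed Gaussian walk.
All are scaled to mean adjacent distance 1. These curves are smooth,
noise-free, and perfectly realizable in 3D — real Hi-C adds balancing
artifacts, population heterogeneity, and conversion-exponent mis-
specification — so passing the benchmark shows the *inverse problem* is
solved correctly, not that biological structures are recovered perfectly.

The corruption protocol down-samples the measured pairs at a given rate
(chain-adjacent pairs are exempt so the adjacency operator stays defined)
and adds symmetric noise $N(\delta, \delta)$ (level 1) or
$N(2\delta, \delta)$ (level 2), where $\delta$ is the minimum retained
squared distance. The distribution notation is read as mean/standard
deviation — with mean/variance the noise would become negligible for
$\delta \ll 1$, defeating its purpose; the `sd` argument makes the
interpretation switchable. Positivity is enforced by per-entry rejection
(100 draws, then a floor at $\delta/100$).

Accuracy metrics: `relative_error_distances()` compares non-squared
distances, $\lVert R - D^{1/2}\rVert_F^2 / \lVert D^{1/2}\rVert_F^2$, in
data units without alignment (so a uniform $(1+\epsilon)$ scaling gives
exactly $\epsilon^2$); `relative_error_coords()` centers, F-norm scales
and orthogonally aligns (reflections allowed) before the analogous
coordinate ratio — an unaligned coordinate error would be meaningless for
a method that cannot observe pose or chirality. Spearman correlations are
computed on measured pairs within a scope (all / intra-domain /
inter-domain). The permutation test for 3D proximity compares a focal
pair against random pairs at the same genomic separation with add-one
smoothing, so p-values are never exactly zero.

Problem sizes used by the test suite and acceptance script — chosen as
the smallest sizes at which the two-scale hierarchy and the full rate
grid are meaningfully exercised: 200 bins for the 9-rate × 2-level × 10-
replicate grid, 300 bins with 3- and 5-domain partitions for assembly,
and 20–60 bins for unit-level oracles.

## Curvature

Local geometry is profiled by fitting quadratics $x(t), y(t), z(t)$ over a
5-bin window ($t = -2, \dots, 2$ in bin-index units; the parametrization
is an implementation choice — arc length would differ only at second
order for near-uniform chains) and evaluating
$\kappa = |r'' \times r'|\,/\,|r'|^3$ at the center. Curvature is
undefined at the two bins on each end and wherever the fitted speed
vanishes; per-chromosome normalization divides by the median over defined
bins. Closed forms (line 0, circle $1/R$, helix $R/(R^2 + c^2)$) are
reproduced to ~1–2%, the discretization error of the 5-point fit.

## Known limitations

* Consensus structure only: population heterogeneity is averaged away, and
  chirality is unidentifiable from distances (reported up to reflection).
* Intra-chromosomal only; inter-chromosomal maps and whole-genome assembly
  are out of scope.
* The distance scale is set by the conversion exponent; only rank-based
  agreement is invariant to it.
* KR balancing assumes the retained sub-matrix has irreducible support;
  unbalanceable rows are dropped with a warning rather than rescued.
* The γ and `d_t` defaults are pragmatic, not canonical; both are exposed
  and tunable.
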