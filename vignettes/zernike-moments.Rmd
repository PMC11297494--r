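---
title: "Volumetric protein shape analysis with 3D Zernike moments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric protein shape analysis with 3D Zernike moments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zernike3d)
```

## The shape model

`zernike3d` treats a protein as a density rather than a list of bonded
atoms. The C-alpha trace is converted to a volume by placing an isotropic
Gaussian on each atom; the resulting density is expanded on the orthonormal
3D Zernike basis over the unit ball,

$$\Omega_{nlm} = \int_{|u| \le 1} f(u)\, \overline{Z_{nlm}(u)}\, du,
\qquad Z_{nlm}(u) = R_{nl}(r)\, Y_{lm}(\theta, \varphi),$$

with order $n \le 40$, degree $l \le n$ of the same parity, and components
$0 \le m \le l$ (negative $m$ follow from conjugate symmetry of a real
density, $\Omega_{n,l,-m} = (-1)^m \overline{\Omega_{nlm}}$). Working with
a volume has three practical consequences: chain connectivity never enters,
quaternary structure is handled exactly like a monomer, and the same
machinery applies to any non-negative density on a grid. The price is that
the method knows nothing about residue correspondences, so it cannot
produce coordinate-level quality metrics of the RMSD family; the
superposition it returns is a volume-overlap alignment.

### Conventions

The basis is orthonormal over the ball,
$\int_{|u|\le 1} Z_{nlm} \overline{Z_{n'l'm'}}\, du = \delta$: the radial
polynomials satisfy $\int_0^1 R_{nl}^2 r^2 dr = 1$
($R_{nl}(r) = \sqrt{2n+3}\, r^l P_k^{(0,\,l+1/2)}(2r^2-1)$, $k=(n-l)/2$)
and the spherical harmonics carry the Condon–Shortley phase. This one
convention is shared by the moment contraction, the descriptors, and the
rotation machinery, and it is pinned by a test that integrates basis
products by brute-force quadrature rather than by trusting any transcribed
formula: at order 6 on a 96³ midpoint grid the Gram matrix is the identity
to ~0.5% (the residual is quadrature error, shrinking with grid
refinement).

## Voxelization

`rasterize()` samples each atom's Gaussian at voxel centers inside a
truncation radius (default $4\sigma$) and renormalizes each truncated,
discretely sampled kernel so the atom's full weight lands on the grid.
Renormalization is what makes three properties exact rather than
approximate: total grid mass equals total atom weight to machine
precision, the contribution is exactly linear in the weights, and
translating a cloud by whole voxels shifts the grid without changing any
value. Without it the $4\sigma$ spherical cutoff alone discards
$P(\chi^2_3 > 16) \approx 1.1\times10^{-3}$ of each Gaussian's mass.

Defaults are 1 Å voxels and $\sigma = 1.5$ Å — a smooth, protein-scale
density in which a medium-sized chain occupies a grid on the order of
100³ voxels — with padding chosen so the truncated kernels never clip at
the grid boundary. Gaussians are *sampled*, not integrated over voxels:
sampling keeps the operation exactly linear and, at $\sigma$/edge = 1.5,
the lattice-discretization error of a Gaussian is far below every
tolerance used here.

### The unit-ball frame

Moments are defined on $|u| \le 1$, so each grid needs a translation and
isotropic scale. The center is always the density centroid. For the radius
two conventions are offered:

* `max_extent` — radius = farthest occupied voxel plus half a voxel
  diagonal. Strict containment; the radius of an elongated shape is set by
  its longest dimension.
* `gyration_multiple` (default) — radius = `radius_param` × radius of
  gyration. Size-stable and less sensitive to outlying density; whatever
  falls outside the ball is excluded from the moment sums and the clipped
  mass fraction is reported.

The default `radius_param = 3.2` was fixed once against the package's
synthetic fixtures (globular anisotropic clouds and helical traces at the
default voxelization): the clipped fraction is zero to well below
$10^{-6}$. For unusually elongated or ring-like densities `max_extent` is
the safe choice.

## From geometric to Zernike moments

The computational route is the classical two-step one, organized so the
expensive part is dense linear algebra:

1. **Geometric moments** $M_{rst} = \sum_v f_v u_1^r u_2^s u_3^t\, du^3$
   for all $r+s+t \le N$ are computed by separable per-axis power tables:
   contract the grid with the $x$-powers, reshape, contract with the
   $y$-powers, reshape, contract with the $z$-powers. This is
   mathematically identical to the naive triple loop (a test pins the
   agreement at $10^{-12}$ relative) but runs as three matrix products.
2. **Contraction**: $\Omega_{nlm} = \sum_{rst} \overline{\chi_{nlm,rst}}
   M_{rst}$, where $\chi$ are the monomial coefficients of the basis
   polynomials. $\chi$ is stored as one sparse matrix (6391 × 12341 with
   5.6M nonzeros at order 40), so a whole batch of structures is one
   sparse–dense product — `batch_moments()` stacks the geometric-moment
   vectors as columns and is required by test to agree with the looped
   path to $10^{-12}$. This stacked-array formulation is also the seam
   where an alternative array backend could be substituted.

### The coefficient cache and numerical precision

Every order-dependent table lives in a `zernike_cache`: log-factorials,
$\chi$, and per-degree Wigner prefactors. Factorial products are assembled
in log space and exponentiated only in final combined form; a direct
factorial construction overflows `double` well before order 40, while the
log-space tables are finite (asserted at build time). Two closed forms
keep individual coefficients cancellation-free: the solid-harmonic
expansion in $(x+iy)$, $(x-iy)$, $z$, and a hypergeometric form of the
radial coefficients in which each monomial coefficient is a single signed
product of Gamma factors.

Individual $\chi$ entries still reach $\sim 10^{20}$ at order 40 — an
intrinsic property of the basis, not of the storage — so the *contraction*
at high order loses relative accuracy for small high-$n$ moments through
cancellation. This is the known precision ceiling of the monomial route;
the package therefore validates exactness at moderate order (the
$10^{-9}$-level oracle tests run at order 8) and validates finiteness and
stability, not digit-level accuracy, at order 40.

Caches persist via `save_cache()`/`load_cache()` as a single serialized
container with a schema version; round trips are bit-exact, a cache built
at order $N$ serves any lower order through `truncate_cache()` (asserted
to match a natively built lower-order cache at $10^{-12}$), and corrupted
files fail with a cache-format error rather than silently.

## Rotation-invariant descriptors and similarity

Rotations act unitarily within each $(n,l)$ block, so the per-block norms

$$F_{nl} = \Big(|\Omega_{nl0}|^2 + 2\sum_{m=1}^{l} |\Omega_{nlm}|^2\Big)^{1/2}$$

are rotation-invariant. Invariance is tested two ways: under the 24 proper
octahedral rotations applied as *exact voxel permutations* the descriptors
agree to $10^{-8}$ (observed: $10^{-14}$, pure floating-point noise), and
under arbitrary-angle rotations of the point cloud followed by
re-rasterization they agree to $10^{-2}$ relative (observed: a few
$10^{-5}$; the residual is resampling, not the moments).

Two similarity scores are provided, both symmetric and bounded in [0, 1]:
cosine (default) and normalized L1, `1 - Σ|a-b| / Σ(|a|+|b|)`. Neither is
the trained composite score used by earlier shape-retrieval software —
those learned weights are not public — so both are deliberately generic
and labeled non-canonical. Descriptors can be truncated before scoring to
compare order-20 and order-40 pipelines on equal footing.

The noise-degradation check deserves a note on design: descriptors of
noise-corrupted grids are computed *in the clean grid's frame*, with the
same noise realizations rescaled across amplitude levels (common random
numbers). Recomputing the frame per noisy grid would mix frame drift —
noise mass far from the object moves the centroid and gyration radius —
into what is meant to be a pure descriptor-stability measurement, and the
paired-seed design removes Monte-Carlo jitter from the median curve. Under
that protocol the median cosine self-similarity decreases monotonically
with noise amplitude.

## Canterakis normalization and superposition

A moment set is oriented by its degree-2 block. The six quadratic monomial
moments (and the mass) are a linear image of $\Omega_{000}$,
$\Omega_{200}$ and the $\Omega_{22m}$ block; inverting that $7\times7$
linear map — built numerically from the cache's own $\chi$ rows, so no
separately transcribed formula can disagree with the contraction —
recovers the second-order density tensor. Its eigendecomposition
(descending eigenvalues; each eigenvector's largest component made
positive; frame forced proper) gives the principal rotation, and composing
with the four proper sign flips `diag(±1,±1,±1)` of determinant +1 yields
four candidate orientations, each carrying its fully rotated moment set —
the "alternative moments".

Rotating moments without touching voxels uses the Wigner-D action per
degree: ZYZ Euler angles are extracted from the rotation matrix (with the
usual special-casing at $\beta \in \{0, \pi\}$), and the small-d matrices
are evaluated from the explicit factorial sum with log-space prefactors
cached per degree. The action is verified against the voxel-domain oracle
(rotate the cloud, re-rasterize, recompute) and satisfies composition to
$10^{-10}$; an exact identity input returns the moments bit-for-bit.

`superpose()` evaluates the real part of the complex inner product for all
moving × fixed candidate pairs and picks the maximum. Two choices are
flags because no canonical convention exists: blocks with $n \ge 2$ enter
the product by default (degree 0 carries no orientation information, and
degree 1 vanishes in centroid frames anyway), and vectors are not
norm-scaled by default (`scale_vectors = TRUE` makes the self-score an
upper bound for every cross-score, which the unrelated-shapes test
exploits). The winning pair $(i, j)$ gives
$R = R_j^{fixed\,T} R_i^{moving}$, and the returned 4×4 transform composes
translate(−moving center) → scale(moving) → $R$ → unscale(fixed) →
translate(+fixed center), so structures of different sizes superpose
correctly.

**Degenerate shapes.** A sphere-like or axially symmetric density has no
stable degree-2 frame. When the relative eigenvalue gap falls below
`gap_tol` (default 0.01, i.e. 1% of the leading eigenvalue — comfortably
below the ≥20% gaps the anisotropic fixtures guarantee, comfortably above
numerical noise), `normalize_moments()` raises a classed
degenerate-normalization error instead of returning an arbitrary frame.
Higher-order tie-breaking is a documented extension point
(`degenerate_handler`), not a built-in heuristic: any rule implemented
here would be an invention, and a wrong silent frame is worse than an
honest error. Mirror images are likewise out of scope — only proper
rotations are enumerated, so enantiomers will not superpose.

## Synthetic data: what it does and does not emulate

All tests run on synthetic fixtures, generated in code and seeded:

* `make_asymmetric_cloud()` — Gaussian clouds with axis spreads in ratio
  1 : 0.65 : 0.4 (default overall spread 5 Å, protein-like in size),
  redrawn within the seeded stream until the second-moment eigenvalue gaps
  are at least 20% of the leading eigenvalue. This guarantees the
  anisotropy that principal-frame normalization needs, which is exactly
  what a test of *frame recovery* should guarantee.
* `make_helix_cloud()` — an ideal helical trace (rise 1.5 Å, twist 100°,
  radius 2.3 Å, the textbook alpha-helix geometry), smooth and
  connectivity-free. A finite discrete helix's principal axis is tilted
  off its geometric axis by a small angle, so the generator finishes with
  an exact alignment rotation; the leading eigenvector is z to machine
  precision, which orientation tests rely on.
* `rigid_motion` / `random_motion` — quaternion-uniform rotations plus
  uniform translations, seed recorded.

These fixtures emulate the *geometry* the method consumes: anisotropic
compact shapes, elongated shapes, known rigid motions. They do not emulate
side-chain density, atom-type weights, crystallographic or cryo-EM map
noise, missing density, or symmetric oligomers. Consequently, passing
tests demonstrate correctness of the mathematics and robustness to rigid
motion and additive noise — not retrieval performance on real structure
collections, which depends on the score and order chosen, nor behaviour on
near-symmetric assemblies, where normalization legitimately refuses.

## Problem sizes and tolerances used in validation

The validation suite runs, by the package's own choice of operating
points: quadrature orthonormality at order 6 on 96³; contraction-vs-direct
integration at order 8 on 16³ (tolerance $10^{-9}$, observed $10^{-14}$);
descriptor invariance at order 12 (all 24 exact rotations at $10^{-8}$;
resampled at $10^{-2}$); order-40 finiteness on a 100³ grid; rigid-motion
recovery over 100 seeded motions at order 20 on a 48-point cloud (mean
rotation error < 2°, max < 5°, post-transform RMSD < 1 voxel edge;
observed: ~0.02–0.13° mean, ~10⁻⁴ Å RMSD); batch-equals-loop at
$10^{-12}$ over 8 grids; and bit-exact cache round trips at orders 20 and
40. `scripts/acceptance.R` recomputes all of these from a single `--seed`
and writes the measured values as JSON.

## Known limitations

* Relative accuracy of small, high-order moments degrades by cancellation
  (see above); order 40 is supported and stable but its extra components
  are noisier than the order-20 core.
* The superposition is volume-based: no residue correspondence, no RMSD
  optimality, no flexible or hinge alignment.
* Near-degenerate second-order tensors (symmetric shapes) stop
  normalization by design; supply a `degenerate_handler` to override.
* Only proper rotations are considered; mirror ambiguity is not resolved.
* Similarity scores are generic (cosine / normalized L1), not calibrated
  against any retrieval benchmark; absolute score values should not be
  compared across different orders or voxelization settings.
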