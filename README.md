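# zernike3d

Volumetric protein shape analysis with 3D Zernike moments, in R.

Protein structures are usually compared through their atomic coordinates,
which ties the comparison to chain connectivity and residue pairing.
Volumetric methods instead treat a structure as a density: they apply
equally to monomers and assemblies, need no sequence alignment, and give
compact, rotation-invariant shape fingerprints that scale to large
structure collections. `zernike3d` implements that pipeline end to end for
people doing structural bioinformatics in R: shape descriptors for
similarity screening, and moment-based structural superposition returning
an explicit transform matrix.

## What it computes

Starting from the C-alpha atoms of a PDB/mmCIF file (or any weighted point
cloud), the package:

1. **Voxelizes** the cloud as a Gaussian mixture: each atom contributes an
   isotropic Gaussian (default sigma = 1.5 Å) sampled on a cubic grid
   (default 1 Å voxels).
2. Maps the density into the **unit ball** `|u| <= 1` (centroid translation
   plus isotropic scaling) and computes complex **3D Zernike moments**

   `Omega[n,l,m] = ∫_{|u|<=1} f(u) conj(Z_nlm(u)) du`,  `Z_nlm = R_nl(r) Y_lm(θ,φ)`,

   up to order `n <= 40`, with an orthonormal basis
   (`∫ Z Z'* du = δ`). The computation goes through geometric (monomial)
   moments obtained by separable per-axis contractions, followed by one
   sparse matrix product against a precomputed coefficient table — the
   vectorization that makes batched, high-order computation cheap. All
   factorial-derived coefficients are assembled in log space so the tables
   stay finite at order 40.
3. Reduces moments to **rotation-invariant descriptors**
   `F[n,l] = sqrt(|Omega[n,l,0]|^2 + 2 Σ_{m>0} |Omega[n,l,m]|^2)` and scores
   structure pairs with cosine or normalized-L1 **similarity** in [0, 1].
4. Performs **Canterakis normalization**: the degree-2 moment block defines
   a principal frame; composing it with the four proper sign flips gives
   four "alternative moment" sets per structure, each with its rotation
   matrix. **Superposition** picks the cross-structure candidate pair with
   the highest dot product and composes the 4×4 homogeneous transform
   (translate, scale, rotate, unscale, translate) mapping the moving
   structure onto the fixed one.

## Worked example

```r
library(zernike3d)
cache <- build_cache(20)               # coefficient tables up to order 20

cl  <- make_asymmetric_cloud(48, spread = 5, seed = 11)   # synthetic C-alpha cloud
mo  <- random_motion(99)                                  # seeded rigid motion
cl2 <- apply_motion(cl, mo)

grid  <- rasterize(cl)                 # 1 A voxels, sigma 1.5 A
frame <- unit_ball_frame(grid)
zm    <- zernike_moments(geometric_moments(grid, frame, 20), cache)
desc  <- invariants(zm)

res <- superpose_clouds(cl2, cl, cache)
moved <- apply_transform(cl2$coords, res$transform)
sqrt(mean(rowSums((moved - cl$coords)^2)))   # RMSD after superposition
```

which prints

```
voxel_grid: 31 x 26 x 22 voxels, edge 1 A, mass 48
unit_ball_frame: center (-1.577, 0.121, 0.031) A, scale 0.051071 1/A, clipped 0
zernike_moments: order 20, 946 slots, |Omega[0,0,0]| = 0.00312415
invariant_descriptor: order 20, 121 (n, l) pairs, norm 0.0144217
superposition_result: score 0.00019822, pair (2, 1)
post-transform RMSD: 0.0001 A
cosine similarity (rigid copy): 1.000000
```

The grid carries the cloud's full weight (mass 48 for 48 unit-weight
atoms); the order-20 expansion has 946 complex moments and 121 invariant
components; the recovered transform undoes the random rigid motion to a
10⁻⁴ Å RMSD; and the rotated copy's descriptor is identical to the
original's, as rotation invariance demands.

A thin command-line wrapper is installed under `inst/cli/zernike3d`:

```sh
Rscript inst/cli/zernike3d compute structure.pdb out --order 20
Rscript inst/cli/zernike3d similarity a.pdb b.pdb
Rscript inst/cli/zernike3d superpose moving.pdb fixed.pdb transform.json
Rscript inst/cli/zernike3d cache build coeffs.zcache --order 40
```

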