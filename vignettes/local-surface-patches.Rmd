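---
title: "Local surface patches: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local surface patches: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lspatch)
```

# The method

`lspatch` predicts which ligand type binds a protein pocket by comparing
the pocket against a database of pockets with known ligands. Instead of
one global shape descriptor per pocket, the pocket surface is cut into
overlapping local patches, each encoded independently, and two pockets are
compared by *partially* matching their patch sets. Only the regions that
actually look alike contribute to the score, which is what makes the
method robust to pockets of the same ligand that differ in their flexible
parts.

The pipeline has five stages:

1. **Surface.** The protein is rasterized on a voxel grid (0.5 Å default)
   and the solvent-excluded surface (SES) is computed with a rolling-probe
   approximation: dilate the van der Waals solid by the probe radius
   (1.4 Å), flood-fill the solvent from the grid boundary, re-erode by the
   probe radius, and take the solid voxels adjacent to solvent as the
   surface. Dilation uses the exact analytic distance to the atom spheres;
   the erosion uses an exact Euclidean distance transform. The flood fill
   is 6-connected so the probe cannot leak through diagonal voxel gaps;
   surface adjacency is 26-connected.
2. **Pocket.** Rays are cast from the pocket center — the geometric mean
   of the bound ligand's heavy atoms — in 2000 quasi-uniform directions
   (Fibonacci lattice). Each ray selects the first SURFACE voxel it
   traverses. The union of hits is dilated two rings along the surface
   graph (see *Ray casting* below), reduced to its largest connected
   component, and holes are filled to a fixpoint.
3. **Seeds and patches.** Seed points are pocket surface points closer
   than 1.5 Å to a surface atom and at least 3 Å from every previously
   accepted seed, scanned in lexicographic (x, y, z) order. Each seed cuts
   one patch: the connected pocket region within 5 Å of the seed. Patches
   overlap by construction.
4. **Descriptors.** Each patch is rasterized into the unit ball and
   expanded in the orthonormal Zernike–Canterakis basis
   $Z_{nlm} = R_{nl}(r)\,Y_{lm}(\theta,\varphi)$ up to order $n = 15$:
   $\Omega_{nlm} = \tfrac{3}{4\pi}\int_{|x|\le 1} f(x)\,\bar Z_{nlm}(x)\,dx$,
   assembled from geometric moments through the Cartesian polynomial form
   of the basis. The rotation-invariant descriptor is
   $F_{nl} = \sqrt{\sum_m |\Omega_{nlm}|^2}$ — 72 values at order 15 —
   normalized to a unit vector.
5. **Matching and scoring.** Patches of two pockets are paired by a
   threshold-gated auction (below). The pocket distance combines the mean
   descriptor distance of matched pairs (`avgZd`), the mean discrepancy of
   inter-seed distances across matched pairs (`rpd`, isometry-invariant),
   and the relative patch-count difference (`pocketSd`):
   $\mathrm{Total} = w_1\,\mathrm{avgZd} + w_2\,\mathrm{rpd} +
   (1 - w_1 - w_2)\,\mathrm{pocketSd}$ with $w_1 = 0.06$, $w_2 = 0.14$.
   Database pockets are ranked ascending; a ligand type $F$ is scored over
   the top $k = 18$ ranks by
   $\big(\sum_{i\le k} \delta_{l(i),F}/\log(i+1)\big)\cdot
   \big(\sum_{i\le k}\delta_{l(i),F}/n_F\big)$ and the argmax is the
   prediction.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `spacing` | 0.5 | Å | voxel edge; ~10 voxels across a patch |
| `padding` | 4 | Å | grid margin beyond the atom spheres |
| `probe_radius` | 1.4 | Å | water-sized rolling probe |
| `n_rays` | 2000 | – | ray directions per pocket center |
| `patch_radius` | 5 | Å | patch cut radius |
| `seed_atom_dist` | 1.5 | Å | seed eligibility: gap to nearest surface atom |
| `seed_min_sep` | 3 | Å | minimum seed separation |
| `surface_atom_dist` | 3.5 | Å | surface-atom cutoff |
| `zernike_order` | 15 | – | descriptor order (72 invariants) |
| `grid_dim` | 32 | – | patch rasterization grid (64 in invariance tests) |
| `td` | 0.30 | – | matching distance threshold; `Inf` = ungated |
| `epsilon` | 0.001 | – | auction bid increment |
| `w1`, `w2` | 0.06, 0.14 | – | score weights |
| `k` | 18 | – | ranks entering the ligand score |

The patch geometry constants (5, 1.5, 3, 3.5 Å), order 15, `td` = 0.30,
the weights and `k` = 18 are the method's published operating point. The
grid spacing, padding, probe radius, ray count, patch grid size and
`epsilon` are not specified by the method description; the defaults above
are this implementation's choices, made once and used everywhere.

# Design choices in detail

## Ray casting

A ray should select the first surface it *encounters*. We walk each ray
through the voxel grid (Amanatides–Woo traversal) and stop at the first
SURFACE voxel. An alternative — selecting the nearest surface *point*
within a fixed perpendicular tolerance of the ray line — breaks down in
concave pockets: when the pocket center sits within ~2 Å of the surface,
near-tangent points next to the origin capture wide ray cones and shadow
everything behind them, collapsing the pocket to a handful of points. The
grid walk has no such pathology and is exact with respect to the
discretized surface.

On a corrugated molecular surface the crests of the atomic bumps shadow
the seams between them, so the raw hit set is a dotted pattern. The union
of hits is therefore dilated two rings along the surface adjacency graph
before the largest-component filter; this is the hole-closing step of the
pocket definition, realized as a morphological operation on the surface
graph.

## Seed eligibility

Seed points must be "close to a surface atom". The SES runs *outside* the
van der Waals spheres, so the Euclidean distance from any surface voxel
center to the nearest atom *center* is at least the atom radius
(≥ 1.7 Å for carbon) — a 1.5 Å cutoff measured center-to-center would
never fire. The cutoff is therefore measured to the atom's van der Waals
sphere surface, $|p - c| - r < 1.5$ Å, the only geometrically consistent
reading.

## Descriptor rasterization

Patches are centered on their centroid (a `center = "seed"` option
exists) and scaled so the farthest point lies at 0.7 of the unit ball,
keeping mass away from the boundary where the radial polynomials
oscillate. Each surface point is rasterized as a small ball with radius
equal to the surface sampling pitch: a bare point set at grid 64 leaves
rotation-variant gaps between occupied voxels and would spoil the
invariance the descriptor exists to provide. The Zernike conversion
coefficients are computed once per order from the associated-Legendre
expansion of the solid harmonics, cached, and validated in the test suite
against numerical integration (orthonormality of the basis to 1e-2 at
grid 64, and moment assembly against direct integration to 1e-10).

## The auction matcher

Weights are $C - d_{ij}$ with $C = 2$, the diameter of the unit sphere of
descriptors, so every admissible pair ($d_{ij} < t_d$) has positive
weight and the optimum favors matching as many similar patches as
possible. Patches of the database pocket bid for query patches; prices
rise by the classic increment (best net minus second-best net plus
$\varepsilon$). Two completions of the published narrative were needed:

* **Profit exit.** A patch whose admissible partners all have
  non-positive net value at current prices exits unmatched. Without this
  rule, two patches whose only admissible partner coincides outbid each
  other forever and only an iteration cap stops them — at an arbitrary
  snapshot. With it, termination is guaranteed: every bid raises a price
  by at least $\varepsilon$ and prices are bounded by $C$.
* **No premature cap.** A hard cap of $10\,n_A$ bids stops adversarial
  instances (about 4% of uniform-random 6×6 matrices) before the
  $\varepsilon$-equilibrium is reached. Since termination is already
  guaranteed, the implementation runs to convergence by default; the
  capped behavior is available through `max_iter`. At convergence the
  matching is $\varepsilon$-optimal, and on random test instances it
  reproduces the exact dynamic-programming optimum.

## Scoring conventions

* The rank weight in the ligand score is $1/\log(i+1)$ (natural log,
  rank 1 → $1/\ln 2$); the printed form of the formula is ambiguous about
  the argument of the logarithm, and this reading matches the stated
  intent that higher ranks score higher. The convention is isolated in
  `pocket_score()`.
* The normalization denominator $n_F$ is the number of type-$F$ pockets
  in the database (the stated intent), not the summation limit.
* Zero matched pairs mean no evidence of similarity: `avgZd` and `rpd`
  are undefined and the total score is `Inf`, ranking the pair last.
* A single matched pair leaves `rpd` without a pairwise term; it is
  defined as 0 with a warning, and the $n_A/N$ penalty in `avgZd` still
  applies.
* "Shape only" mode drops the size term and renormalizes the weights to
  $w_1' = 0.3$, $w_2' = 0.7$; `renormalize = FALSE` keeps the raw
  $0.06/0.14$ combination.

## Evaluation conventions

Per-query ROC curves follow the retrieval definition: the top $k$
database pockets for $k = 1..N{-}1$ give one (FPR, TPR) point each, the
curve is anchored at (0,0) and (1,1) and integrated trapezoidally.
Per-ligand AUC is the mean over queries of that ligand; the overall
figure is the **unweighted** mean over ligand types (the alternative —
weighting by query count — is not used). Top-$n$ success counts queries
whose true ligand is among the $n$ best-scoring types; when every type
scores zero the rank-1 pocket's ligand is taken as the (low-confidence)
prediction.

# The synthetic generator

Real benchmark sets require structure downloads, so the test conditions
are defined by a synthetic generator (`make_pocket_dataset()`). It builds
pseudo-proteins — carbon-like atoms (r = 1.7 Å) on a 1.5 Å lattice
filling a slab — and carves one of four cavity classes: a hemispherical
**cap**, an elongated **groove**, a rectangular **cleft** and an enclosed
**tunnel**. The classes differ in local patch geometry and in pocket size
(seed count), as real ligand classes do. Carved regions are generous
enough that the *effective* void (carve minus atom radius, smoothed by
the probe) remains enclosed with a narrowed opening; escaping rays then
climb away from the outer faces, which keeps the extracted pocket stable
under rotation. Each member is randomly rigidly rotated and its atom
coordinates jittered with isotropic Gaussian noise (default
$\sigma$ = 0.15 Å, the order of coordinate uncertainty in a good X-ray
structure). All randomness flows through one seeded generator, so a fixed
seed reproduces the database bit for bit.

What the generator does **not** emulate: real chemistry (element mix,
bonding geometry), side-chain texture, partial ligand exposure, or the
shape overlap between related ligand classes (ATP/AMP, FAD/NAD) that
makes the real benchmark hard. Passing the end-to-end separation test
therefore shows that the pipeline preserves and discriminates shape
classes through all of its stages — not that real pockets of nine ligand
types would separate at the same rates.

# Problem sizes and numerical choices

The test suite uses a 4-class × 10-pocket dataset (seed 20260101,
~40–70 patches per pocket) for the end-to-end and threshold checks, 200
random rotations at grid 64 for descriptor invariance, 100 random 6×6
instances against the exact matcher oracle, and 1000 permutations of a
100-pocket nine-class composition for the random-retrieval baseline.
Moment arithmetic is double precision; descriptors are serialized with 9
significant digits; matching tie-breaks are deterministic (lowest query
index wins, FIFO queue), so repeated runs are byte-identical.

Degenerate inputs are handled explicitly: single-point patches rasterize
to one voxel; an all-zero descriptor is an error; seeds with no pocket
points in range are dropped with a warning; `k` larger than the ranking
is clamped with a warning.

# Known limitations

* The SES is voxel-accurate (one voxel diagonal), not an analytic
  triangulated surface; descriptors inherit a discretization noise floor
  of roughly 0.01–0.02 in descriptor distance at grid 32.
* Pocket extraction needs a center in open solvent; centers buried in the
  solid see the far side of the protein first.
* Only shape is encoded — no electrostatics or other physicochemical
  surface properties.
* The auction is asymmetric (query vs database roles); `N(A→B)` and
  `N(B→A)` may differ, which is inherent to the method.
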