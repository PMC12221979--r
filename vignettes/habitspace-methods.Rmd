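---
title: "Crystal habit analytics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crystal habit analytics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitspace)
```

# The problem

The external shape of a crystal — its habit — controls filtration,
flowability, dissolution and downstream processing of crystalline
products. Growth simulation campaigns produce thousands of particle
shapes, each exported as a surface point cloud, and the analyst needs
(i) a reproducible low-dimensional description of each shape,
(ii) a classification into the habit vocabulary the field uses
(blocks, needles, laths, plates), and (iii) a way to see how shapes
relate to and morph into one another across a parameter space.

`habitspace` implements that pipeline end to end: a generator of
labelled synthetic habits (so everything is testable without any
simulation campaign), aspect-ratio and Zingg classification,
spherical-harmonic shape descriptors, voxelization, a disentangling
autoencoder (DAE) over voxel grids, and quantitative latent-space
analysis including decoded morphing trajectories.

# Shape measures

## Aspect ratios and the Zingg chart

Each particle cloud is summarized by three orthogonal lengths
S ≤ M ≤ L, computed as the singular values of the centred coordinate
matrix divided by √N — i.e. RMS extents along the principal axes. The
division by √N makes the values sample-size independent; only the
ratios are used downstream, so the open question of whether a given
reference pipeline normalizes its singular values is immaterial to
every reported quantity.

The two ratios S:M and M:L place each particle on the Zingg chart and
are thresholded at 0.66 (the printed convention; the threshold is a
parameter of `zingg_classify()`):

* block: both ratios > 0.66,
* needle: S:M > 0.66, M:L ≤ 0.66,
* plate: S:M ≤ 0.66, M:L > 0.66,
* lath: both ≤ 0.66.

Equality at the threshold is assigned to the ≤ branch, because a block
is defined by ratios *greater than* the threshold. The classic sanity
check is the cube: its characteristic lengths are the edge a, the face
diagonal √2·a and the body diagonal √3·a, so S:M = 1/√2 ≈ 0.707 and
M:L = √2/√3 ≈ 0.816, and a cube classifies as a block.

Surface-sampled clouds yield slightly larger ratios than the uniform
solid of the same polyhedron (boundary mass sits at the extremes), so a
shape whose solid-oracle ratio is just below 0.66 can measure just
above it from its surface cloud. The package computes ratios from
whatever cloud it is given and documents rather than corrects this
bias; generator ground truth uses the exact solid second moment
(tetrahedral decomposition of the hull), and agreement tests exclude a
±0.08 band around the threshold.

## Convex hull features

Surface area, volume and their ratio come from a 3-D convex hull
(incremental algorithm with outward-oriented triangular facets,
implemented in C++ in this package). Volume and the solid centroid are
computed by signed tetrahedra; the same decomposition gives the exact
uniform-solid covariance used as the generator's ground-truth oracle.

## Spherical-harmonic shape descriptors

For a star-shaped (here: convex) particle, the boundary is a
single-valued radial function r(θ, φ) about the solid centroid.
Expanding r in orthonormal complex spherical harmonics up to degree
l_max = 10 and keeping the coefficient magnitudes for 0 ≤ m ≤ l gives a
66-dimensional descriptor (for real r the m < 0 coefficients are
conjugates and add no information; the count (l_max+1)(l_max+2)/2 = 66
matches the m ≥ 0 convention). Magnitudes are stored in (l, m)
lexicographic order, so Mag_0..Mag_5 are Y00, Y10, Y11, Y20, Y21, Y22:
Mag_0 is the mean radius, Mag_1/Mag_2 capture dipole-like asymmetries
along z and in the xy-plane, and Mag_3..Mag_5 quadrupolar
elongation/flattening, with Mag_3 the z-elongation term. Descriptors
are evaluated in the fixed Cartesian frame — deliberately not rotation
invariant, so coefficient-by-coefficient comparisons between aligned
shapes are direct.

Numerics: the quadrature is Gauss–Legendre in cos θ crossed with a
uniform φ grid (defaults n_θ = 32, n_φ = 64; weights sum to 4π). The
product rule is exact for integrands of spherical-polynomial degree
2·l_max, which is the precision needed to project a degree-l_max
function; `sh_expand()` refuses quadratures below n_θ = l_max + 1 or
n_φ = 2·l_max + 1 rather than silently aliasing. A truncation at
degree 10 follows near-equant polyhedra closely (median max relative
radius error below 10% for generated blocks) but cannot follow the
sharp radial features of extreme laths or needles, where the maximum
pointwise error grows well beyond that; tests assert the equant-shape
bound and the monotone growth of error with elongation rather than a
blanket bound the mathematics does not support.

# The synthetic habit generator

The generator stands in for a kinetic Monte Carlo growth simulator's
XYZ surface output, on the grounds that the simulated equilibrium
shapes of interest are simple convex polyhedra. Each habit is the
bounded intersection of facet halfspaces n_i · x ≤ d_i (a Wulff-style
construction), realized by convex-hull duality and sampled uniformly
on its surface with per-facet counts proportional to facet area.

Three crystal systems are emulated through their facet families:

* monoclinic — three unequal facet-pair distances, β drawn uniformly
  in [95°, 125°], optional corner truncations (probability 1/2,
  cutting 85–99% of the corner support) for facet variety;
* tetragonal — γ = 90°, the four in-plane facets share one distance
  (square cross-section), optional symmetric edge cuts;
* hexagonal — γ = 120°, six in-plane facets share one distance
  (regular hexagonal cross-section).

Aspect-ratio targets are drawn log-uniformly in [0.15, 1] per ratio
and redrawn until the realized polyhedron's exact solid-oracle class
matches the request. Because tetragonal and hexagonal prisms have two
equal in-plane extents, one of the two ratios is pinned near 1 and the
lath quadrant (both ratios ≤ 0.66) is geometrically inaccessible —
requesting laths in those systems is a configuration error, and the
γ = 120° cell geometry (rhombus diagonals a√(2±2cos α) with α = 60°)
is verified in the test suite. A small isotropic jitter
(σ = 0.3% of the maximum extent, configurable) emulates growth-surface
roughness at a level that leaves Zingg labels stable.

What the generator does *not* emulate: surface topography correlated
with facet chemistry, concavities, polycrystallinity, or the
parameter-space correlation structure of a real growth study. Passing
tests therefore demonstrate that the analytics recover controlled
geometric factors from convex particles, not that they resolve every
phenomenon of real growth data.

# Voxelization

Clouds are aligned (principal axes to Cartesian axes, L→z, M→y, S→x,
signs fixed by non-negative third moments — the convolutional model is
not rotation equivariant, so alignment is required), normalized to the
unit ball, rasterized into a binary occupancy grid over [−1, 1]³ at
resolution 64, zero-padded if needed, and block-max downsampled
(factor 2, the max over each 2³ block) to the 32³ model input. The
source resolution of 64 is the package's choice so that one factor-2
block-max reaches 32³; the decoded-volume binarization threshold is
0.5. Convex-solid filling marks voxels whose centre lies inside the
hull plus the voxels containing input points; the union guarantees the
solid occupancy contains the surface occupancy at every resolution.
Occupancy is binary at source resolution, so occupied fractions track
the hull volume only to within about one voxel layer per face —
axis-aligned faces sitting just past a row of voxel centres are the
worst case — and block-max downsampling dilates thin shapes by up to
one source voxel per side, slightly inflating their measured aspect
ratios.

# The disentangling autoencoder

The encoder is a stack of strided 3-D convolutions (kernel 4, stride
2, padding 1) halving the grid side per layer, a linear head to the
latent space, and then an *exactly orthogonal* learned map: the
product of Givens plane rotations G(i, j, θ_ij) over all d(d−1)/2
index pairs (15 angles for the 6-D latent default). Because training
updates only the angles, the map is orthogonal by construction at
every step — its Gram deviation is logged each epoch and stays at
floating-point round-off — which keeps the latent dimensions linearly
independent, the property that makes individual dimensions align with
independent factors of shape variation. The decoder mirrors the
encoder with transposed convolutions and a sigmoid output in [0, 1].

Choices made where the architecture was genuinely open: four conv
blocks with channels 8/16/32/64 at 32³ input; per-voxel binary
cross-entropy on the [0, 1] occupancy targets (mean-squared error is
available); Adam with learning rate 10⁻³; batch 32; He initialization;
orthogonal map placed after the encoder's linear head (placing it at
the decoder input instead is an equivalent reparameterization of the
same constraint); angles initialized at zero. All are exposed in
`dae_config()`. Layers are implemented as im2col/col2im (C++) plus
BLAS matrix products, with analytic backpropagation verified against
central differences in the test suite.

Reconstruction quality is scored by two volume metrics: 3-D SSIM
(uniform 7³ window over interior positions, stabilization constants
(0.01·range)² and (0.03·range)², range 1, population moments) and NCC
(Pearson correlation of the flattened volumes). Both live in [−1, 1]
and equal 1 for identical volumes; the reference baseline for
reconstructions is the SSIM of each input against the dataset-mean
volume.

# Latent-space analysis

`feature_correlations()` reports the Pearson correlation of each
latent dimension with S:M, M:L, surface area, volume and SA:V —
correlation rather than raw covariance, because it is scale-free and
matches the [−1, 1] range in which such latent–feature relationships
are quoted; `harmonic_correlations()` does the same against
Mag_0..Mag_5. Two projections serve the 2-D maps: selection of the two
latent dimensions most correlated with the two aspect ratios (no
fitting), and a nonmetric MDS embedding of the full latent space
(Kruskal stress over Euclidean latent distances, classical-scaling
initialization, seed-deterministic). Class centroids are arithmetic
means per Zingg class, and `interpolate_trajectory()` decodes evenly
spaced points on the latent segment between two centroids (8 steps by
default, matching the panel counts such morphing figures typically
show), measuring each decoded volume's aspect ratios through the
voxel-centre cloud at the 0.5 threshold. A decoded step that is empty
at the threshold is flagged, not fatal.

# Problem sizes and reproducibility

The package's study-sized configuration is 32³ grids with channels
8/16/32/64. The bundled acceptance and test runs use a proportionally
smaller configuration — 1,200 balanced habits, 16³ grids (source
resolution 32), channels 8/16/32, 40 epochs, batch 32 — which trains
in a few minutes on one CPU core while exhibiting the same qualitative
behaviour: two distinct latent dimensions whose absolute correlations
with S:M and M:L exceed 0.6 by a wide margin (≈0.9 in our runs), mean
reconstruction SSIM far above the mean-volume baseline, decoded
class-centroid trajectory endpoints that classify as their own
classes, and no lath classifications in the tetragonal and hexagonal
sweeps. Every stochastic step — generation, initialization, batching,
embeddings — is seeded, and `run_pipeline()` records seeds, parameters
and artifact hashes in a JSON manifest; identical configs reproduce
non-training artifacts byte for byte.

# Known limitations

* Convex, star-shaped particles only; no concave or multi-domain
  shapes (the radial map would be multivalued).
* Descriptors and the model operate on aligned shapes; arbitrary
  rotations require re-alignment first.
* The SH truncation at degree 10 under-resolves extreme aspect
  ratios (documented above).
* Binary occupancy: no partial-volume rasterization.
* Training determinism is per-platform (BLAS summation order may
  differ across builds).
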