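---
title: "Symmetry-compressed OSEM reconstruction for dual-head planar PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry-compressed OSEM reconstruction for dual-head planar PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planarpet)
```

## The imaging model

A dual-head planar PET scanner consists of two opposed rectangular crystal
panels. Every ordered pair of crystals, one per head, defines a line of
response (LOR); a coincidence event is assigned to the LOR joining the two
crystals that detected the annihilation photons. With $g_i$ the measured
counts on LOR $i$, $x_j$ the unknown activity in voxel $j$, and
$h_{ij}$ the probability that an annihilation in voxel $j$ is detected on
LOR $i$ (the system response matrix, SRM), the measurements are modelled as
independent Poisson variables

$$ g_i \sim \mathrm{Poisson}\!\left( \sum_j h_{ij}\, x_j \right), $$

with randoms and scatter set to zero. `planarpet` solves this model with
ordered-subset expectation maximization (OSEM). Starting from a constant
image ($x_j^{(0)} = 1$ on every voxel with nonzero sensitivity), each subset
$S_k$ of LORs contributes the multiplicative update

$$ x_j \leftarrow \frac{x_j}{\sum_{i \in S_k} h_{ij}}
   \sum_{i \in S_k} h_{ij} \frac{g_i}{(Hx)_i}, $$

and one full iteration cycles through all subsets. With a single subset this
is plain MLEM, which enjoys two exactly testable properties the package
verifies numerically: the Poisson log-likelihood never decreases, and after
every full pass the projected counts match the measured counts,
$\sum_j s_j x_j = \sum_i g_i$ with $s_j = \sum_i h_{ij}$ the sensitivity
image.

Subsets are formed from whole LOR *orientations* — the integer crystal
displacement $(\Delta r, \Delta c)$ between the two endpoints — shuffled by a
seeded generator and dealt round-robin. Orientations related by sign flips
$(\pm\Delta r, \pm\Delta c)$ are kept in the same subset so that the
4-member symmetric LOR families the projectors exploit never straddle a
subset boundary; consequently subset sizes are balanced in orientation
*classes* (within one class) rather than in single orientations.

## Why compression is necessary

At full scale the scanner modelled by `default_geometry()` has
$104 \times 72$ double-layered crystals per head, giving
$(2 \cdot 104 \cdot 72)^2 \approx 2.24\times 10^8$ LORs, and the
`default_grid()` of 119 z-planes at quarter-pitch in-plane sampling has
$\approx 1.43 \times 10^7$ voxels. The dense SRM would have more than
$10^{15}$ entries. The planar geometry, however, is highly symmetric:

* **Shift invariance.** Translating a crystal pair and the voxel together by
  whole crystal pitches (ignoring the panel edge) leaves $h_{ij}$ unchanged.
  This holds when the in-plane voxel size is $p/m$ for integer $m$.
* **Reflection symmetry.** Reflections about the x-, y- and z- coordinate
  planes map (LOR, voxel) pairs to pairs with equal response; the z-reflection
  swaps the two heads and negates the voxel slice.
* **Axis interchangeability.** Swapping the roles of the x and y axes also
  preserves the response (both axes share the same pitch).

These operations generate a group of order 16 acting on (LOR, voxel) pairs.
Quotienting by it, a grid with $n$ z-planes (odd, central plane midway
between the heads) needs detector response functions (DRFs) for only
$(n+1)/2$ plane classes, and within a plane only for the in-plane offset
classes of the $m \times m$ voxel phases under reflections and interchange —
3 classes for $m = 4$. The default grid therefore compresses to
$60 \times 3 = 180$ seed DRFs:

```{r}
nrow(plane_classes(119)) * inplane_seed_classes(4)$n_classes
```

Internally every (LOR, voxel) pair reduces to the integer invariant tuple
$(s,\; g_{ux},\; g_{lx},\; g_{uy},\; g_{ly})$ — the signed slice plus the
four crystal-minus-voxel offsets in half-voxel units. Shifts leave the tuple
fixed; reflections negate or swap components; canonicalization takes the
lexicographically greatest image over the group, which in particular has a
nonnegative slice. Because the convention is only required to be *fixed*,
not unique, this choice is as good as any; all arithmetic is integral, so
canonicalization and the transform round-trip are exact.

Boundary effects are handled the way a finite panel requires: seed DRFs are
computed on an *extended* crystal lattice (`extension_margin` indices per
side, defaulting to half the panel plus one) so that every physically
realizable offset has an in-range seed entry, and non-physical crystals are
discarded when the pool is expanded back to real LORs.

## The deterministic detector-response model

Real systems estimate their SRM from measurements or Monte-Carlo photon
transport. This package instead ships a deterministic geometric model,
chosen deliberately: it honours the symmetry group to rounding error, which makes
exact oracle tests possible (a stochastic model could only be tested
statistically), and it is fast enough to rebuild from scratch in tests.

For a voxel and a crystal pair the detection probability is a quadrature
over `n_sub`³ sub-voxel emission points and `n_face`² face patches: a photon
pair emitted isotropically and back-to-back is accepted when one photon
enters the upper crystal face and its collinear partner enters the lower
face, each detected with probability $1 - e^{-\mu L}$ along the slant path
$L = t/\cos\theta$ through a crystal of thickness $t$. Defaults:
$\mu = 0.087\,\mathrm{mm}^{-1}$ (LSO at 511 keV), $t = 20$ mm,
`n_sub = 2`, `n_face = 4`. The absolute scale of the probabilities is a free
model parameter (`scale`); reconstruction is scale-invariant, and all tests
are formulated scale-free.

Two numerical choices matter:

* **Head-swap symmetrization.** A single-sided quadrature (sample the upper
  face, project to the lower) is only z-symmetric up to quadrature error.
  `drf_prob()` therefore averages the upper-face and lower-face fans, making
  the head-swap symmetry exact up to the commutativity of addition — this is
  what lets the symmetry-expanded SRM match a brute-force build at
  $10^{-12}$ relative rather than at quadrature accuracy.
* **Integer-invariant evaluation.** The model is evaluated from the integer
  tuple only, never from absolute coordinates, so shift invariance holds
  *bitwise* and repeated builds are bit-identical.

Entries below `prune_rel` (default $10^{-9}$) of the per-seed maximum are
pruned; the threshold is stored in the pool manifest, never silently
applied. The optional `max_tilt` parameter restricts stored entries to
$|\Delta r|, |\Delta c| \le$ `max_tilt` crystal pitches — an angular
acceptance window that keeps desk-scale studies small; it too is recorded in
the manifest, and lookups outside the window return 0. Energy windows,
coincidence timing, positron range, scatter and dead time are not modelled.

Depth of interaction enters only through the slant attenuation path; the
two DOI layers of the physical detector are counted in the LOR index space
(`lor_count()`) but DRFs are computed for single-layer crystal endpoints,
and reconstruction operates on the front-layer LOR space
(`lor_count(geom, layers = FALSE)`).

## Projector execution schedules

Forward ($Hx$) and back ($H^{\mathsf T}y$) projection are organized the way
the compression suggests: per orientation class, the shift-invariant LORs of
the canonical orientation are expanded through a symmetric family of up to
4 reflections, all sharing one seed DRF. `srm_matrix()` materializes the
scheduled block of $H$ as a `Matrix` sparse matrix by carrying every
canonical seed entry through the group, keeping images whose orientation is
scheduled, and vectorizing the shift expansion; the block is cached per
(store, schedule). The accumulation order is fixed, so projections are
bit-reproducible, and a naive per-element execution path
(`forward_project_naive()`) is kept as a reference: both paths must agree to
$10^{-10}$ relative, which is the package's testable restatement of
"different execution schedules, same projections". A `zero_skip` option
skips zero bins/voxels and is verified to be bit-identical to the plain
path.

## The synthetic study

`derenzo_phantom()` builds a micro-Derenzo-style resolution phantom: one
angular sector per rod-diameter group (defaults 2.4, 2.0, 1.7, 1.35, 1.0,
0.75 mm), rods parallel to z, center-to-center spacing twice the diameter in
the classic triangular arrangement growing outward from the phantom center.
The exact rod count per sector is not prescribed anywhere; the generator
packs the triangular lattice into each sector (edge margin one diameter,
radial margin one radius) and records the resulting rod table as metadata,
so tests assert the group structure and spacing rule rather than a
particular count. Voxelization is by voxel-center inclusion, which
reproduces analytic cylinder volumes to better than 10 % at 0.6 mm voxels
for the 2.4 mm group.

`simulate_measurement()` forward-projects the phantom, scales the projection
to a requested expected total count (default $10^6$), and draws independent
Poisson counts with a seeded generator, returning both the noisy histogram
and the noise-free mean.

What the generator emulates: Poisson counting noise on an exactly known
system model, i.e. the inverse-problem difficulty of the reconstruction.
What it does not emulate: attenuation, scatter, randoms, positron range,
detector energy response, normalization drift. Passing tests therefore
demonstrate the correctness of the compression, projectors and EM iteration
— not robustness to the physics the model excludes.

## Desk-scale problem sizes

The package's own verification studies are sized for a single CPU:

* Oracle tests (brute force vs expansion) run on scanners up to
  $8 \times 8$ crystals and 5 planes, where the full SRM has at most a few
  million entries.
* The resolution study uses a $32 \times 32$-crystal scanner, 9 planes of
  2.4 mm, half-pitch (1.2 mm) in-plane voxels, `max_tilt = 4`, a two-group
  Derenzo (3.6 and 2.4 mm rods — 3 and 2 voxels across), $10^6$ counts, and
  4 subsets. After 24 iterations the peak-to-valley contrast across the
  small-rod group is two orders of magnitude above its 1-iteration value;
  the qualitative claim — more iterations resolve the small rods better — is
  what the acceptance suite asserts, since the precise gain depends on the
  noise seed.

## Degenerate inputs and guards

* Bins with zero projected mean and zero counts contribute nothing to the
  update; zero mean with positive counts is flagged and skipped with a
  warning (the convention that preserves the EM fixed point).
* Voxels with zero subset sensitivity are left unchanged; voxels invisible
  to every subset are initialized to 0 instead of 1.
* An all-zero sensitivity (empty schedule) or an all-zero phantom projection
  is an error, not a silent zero image.
* Geometry/grid fingerprints are embedded in every store, schedule,
  histogram and volume and mismatches are fatal before any compute.
* Even plane counts are rejected: the central plane must lie exactly midway
  between the heads for the z-reflection class structure to exist.
* Axis interchange is dropped from the group (order 8 instead of 16) when
  the row and column lattices are incongruent modulo one pitch
  (`n_rows - n_cols` odd on detector-face grids); all shipped geometries use
  the full group.

## Known limitations

* The geometric DRF model is a stand-in for measured or Monte-Carlo response
  functions; absolute sensitivities and inter-crystal penetration are not
  physical.
* Histograms are dense in the front-layer LOR space, which is comfortable up
  to roughly $10^6$ LORs; the full 224M-LOR scanner is dimensioned
  (`lor_count()`, class counts, seed layout) but a full-scale reconstruction
  additionally needs the sparse histogram path and out-of-core projector
  blocks.
* Subsets balance orientation classes, not raw orientations (see above);
  with very few classes per subset the OSEM speedup saturates accordingly.
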