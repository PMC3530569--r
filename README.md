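# planarpet

Symmetry-compressed OSEM image reconstruction for dual-head planar PET
scanners.

## The problem

Compact small-animal PET systems built from two opposed flat detector panels
achieve high sensitivity, but at a price: a pair of 104 × 72 double-layered
crystal arrays produces more than 224 million lines of response (LORs), and a
119-plane, quarter-pitch voxel grid has more than 14 million voxels. The
system response matrix (SRM) `H` — with `h_ij` the probability that an
annihilation in voxel `j` is detected on LOR `i` — can therefore never be
stored elementwise, yet iterative reconstruction needs it on every iteration.

The planar geometry is highly symmetric, and `planarpet` exploits that:

* **shift invariance** — translating a crystal pair and voxel together by
  whole crystal pitches preserves `h_ij` (when the in-plane voxel size is
  `pitch/m` for integer `m`);
* **reflection symmetry** — reflections about the x-, y- and z- coordinate
  planes preserve the response (the z-reflection swaps the two heads);
* **axis interchangeability** — swapping the roles of the x and y axes
  preserves the response.

Quotienting the (LOR, voxel) space by the group these operations generate,
the default grid needs detector response functions (DRFs) for only
60 z-plane classes × 3 in-plane offset classes = **180 seed voxels**. Every
other SRM element is recovered on the fly by canonicalizing its integer
offset tuple onto a seed. Forward and back projectors expand the seed pool
over shift-invariant LOR families (up to 4 reflection-symmetric LORs per
family), and ordered-subset expectation maximization (OSEM),

```
x_j <- x_j / sum_{i in S} h_ij * sum_{i in S} h_ij g_i / (Hx)_i ,
```

runs on top with orientation-based subsets (MLEM is the 1-subset case). The
DRFs themselves come from a deterministic geometric detection model
(solid-angle quadrature × exponential crystal attenuation, `mu` = 0.087/mm
for LSO at 511 keV) that honours the symmetry group to rounding error, so
the whole compression machinery is verified against a brute-force SRM build
at 1e-12 relative tolerance.

## Worked example

A desk-scale scanner, a two-group Derenzo resolution phantom, a noisy
measurement, and a 10-iteration OSEM reconstruction:

```r
library(planarpet)

geom  <- scanner_geometry(n_rows = 16, n_cols = 16, n_layers = 1)
grid  <- voxel_grid(geom, n_planes = 5, dz = 6, m = 2)   # 1.2 mm voxels
store <- build_seed_pool(geom, grid)
store
#> Seed-DRF store: 3 seeds (3 plane classes x 1 in-plane classes)
#>   9356 canonical entries, prune threshold 1e-09 (relative)

phantom <- derenzo_phantom(grid, derenzo_spec(diameters = c(3.6, 2.4), radius = 16))
sched   <- make_schedule(geom, grid)
sim     <- simulate_measurement(phantom, store, sched, total_counts = 2e5, seed = 1)
sim$counts
#> LOR histogram: 65,536 bins, 16,856 nonzero, total 200040

plan <- partition_subsets(enumerate_orientations(geom), S = 4, seed = 1)
rec  <- reconstruct(sim$counts, store, plan, recon_config(n_iterations = 10))
tail(attr(rec, "log"), 3)
#>    iteration   loglik min_voxel max_voxel flagged_bins
#> 8          8 357453.1         0  38958.31            0
#> 9          9 357493.7         0  39173.89            0
#> 10        10 357520.2         0  39319.19            0

rod_contrast(rec, attr(phantom, "rods"), group = 1)
#> [1] 191.6
```

The log shows the Poisson log-likelihood increasing across full iterations;
`rod_contrast()` is the peak-to-valley ratio across the 2.4 mm rod group —
191.6 means the small rods are cleanly separated from the gaps between them.
Volumes can be written as NIfTI (`write_volume()`), seed pools as Matrix
Market coordinate files plus a JSON manifest (`save_seed_pool()`), and
histograms as dense binary or sparse TSV (`write_histogram()`).

A command-line interface wraps the same pipeline
(`inst/cli/planarpet geometry-info | build-pool | phantom | simulate | recon
| verify-symmetry`); `verify-symmetry --preset tiny` rebuilds a tiny scanner
and checks the expanded SRM against brute force.

## Scope

Randoms, scatter, attenuation, positron range and detector energy response
are not modelled; the two DOI layers are counted in the LOR index space but
reconstruction operates on front-layer LORs. See the vignette
(`vignettes/symmetry-compressed-osem.Rmd`) for the model, the numerical
choices and the design rationale.
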