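---
title: "Growth-driven skin folding: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-driven skin folding: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`morphofold` studies a mechanical route to skin patterning: when an
epidermis grows faster (and stiffer) than the dermis beneath it, the
compressed outer layer buckles into labyrinthine folds — no chemical
patterning system required. The package provides the four ingredients
needed to study this process quantitatively on synthetic toepad-like
geometries: a morphoelastic finite-element simulator, a fold-network
extraction and comparison pipeline, a Bayesian calibration layer that fits
layer parameters to target networks, and a 3D nuclei-detection module that
estimates the per-layer proliferation that drives the growth.

## The mechanical model

Tissue growth is modelled with the multiplicative decomposition
`F = Fe Fg`: the observable deformation gradient `F` factors into a
stress-free growth part `Fg` and an elastic accommodation `Fe`. Growth is
anisotropic and saturating,

```
Fg(t) = I + lambda_N s(t) N⊗N + lambda_T s(t) (I − N⊗N),
s(t)  = 1 − exp(−beta t),
```

with `N` the outward layer normal *in the reference configuration*
(stored per element, never updated during deformation), `lambda_N` and
`lambda_T` the final relative growth along and across `N`, and `beta` the
saturation rate. The elastic response is compressible neo-Hookean,

```
Psi(Fe) = mu/2 (tr(Fe Fe') J^(-2/3) − 3) + K (J − log J − 1),   J = det Fe,
```

whose Cauchy stress has the closed form
`sigma = mu J^(-5/3) dev(Fe Fe') + K (1 − 1/J) I`; the test suite checks
this closed form against central finite differences of `Psi` at 100 random
elastic states. `mu` and `K` derive from `E` and `nu` in the usual way
(`compute_moduli()`). All stresses are relative: the dermis has `E = 1`.

**Discretization and relaxation.** Linear (P1) tetrahedra with a single
quadrature point. Quasi-static states are found by damped explicit
dynamics with lumped *unit* nodal masses — the masses are fictitious at
steady state, so they are chosen for time-step economy rather than
physical fidelity; the step is auto-set from a per-node stiffness bound
and can be overridden. Growth ramps along the simulation clock with
`beta = 1`; relaxation continues until the ramp is essentially complete
(`beta t >= growth_ramp_end`) *and* the maximum nodal residual force falls
below `force_tolerance`. Self-contact of the folding surface is handled by
a node–triangle penalty (linear spring inside `contact_range`, 1-ring
neighbours excluded). Near-incompressible settings (`nu > 0.45`) are
rejected: P1 elements lock there.

Two numerical behaviours deserve a note. First, a perfectly flat slab
past the buckling threshold is an unstable *equilibrium*: a solver started
there with a loose force tolerance can converge onto it before the
instability grows out of the seeded perturbation (at most `1e-4` of an
edge length). For buckling studies, `growth_ramp_end` doubles as a
guaranteed integration horizon; the wrinkling tests use a horizon long
enough for the fastest-growing mode to saturate. Second, the muscle core
is realized as clamped interface nodes rather than a stiff material — it
is rigid by assumption, and stiff elements would only shrink the stable
time step.

**Validation against closed forms.** Three solver-level fixed points are
tested: zero growth must produce no motion; spatially uniform isotropic
growth of a free body must rescale it stress-free by `1 + lambda s`; and a
stiff film on a soft substrate driven past onset must wrinkle at the
classical wavelength `2 pi h (E_f (1−nu_s^2) / (3 E_s (1−nu_f^2)))^(1/3)`,
which the simulator reproduces within 20% (the measured, lab-frame
wavelength sits slightly below the intrinsic one because the film stays
laterally confined while it grows). The wrinkling test uses a slab of
5 classical wavelengths, a 30:1 modulus contrast and 12% tangential film
growth, measured by the power-spectral centroid of the surface profile.

## Fold networks and the two-component metric

A deformed epidermis surface is summarized in four steps:

1. **Minimum principal curvature** per vertex, from the cotangent
   mean-curvature normal and angle-defect Gaussian curvature with Meyer
   mixed-Voronoi areas. Convention: a unit sphere with outward normals has
   `kappa_min = +1`; fold valleys are concave, `kappa_min < 0`. Boundary
   vertices inherit neighbour averages.
2. **Fold mask**: vertices below the `q`-quantile of `kappa_min` *and*
   below zero. The quantile (default 0.3) sets how much of the surface
   counts as valley; the hard zero cap keeps flat or convex regions out
   regardless of `q`. An optional curvature-magnitude floor
   (`min_curvature`) additionally rejects shallow valleys: on a nearly
   flat surface the quantile would otherwise select numerical ripples
   whose curvature is orders of magnitude below a true fold's
   `~1/thickness`, so "no-pattern" checks use a floor of about
   `1/(10 h_f)`.
3. **Skeletonization** on the 2D raster projection of the masked region
   (ventral view by default; pixel 0.8 × median projected edge length),
   thinned with Guo–Hall, then traced into a graph whose nodes are
   junctions/endpoints and whose edges are polylines with exact arc
   length. Graph simplification merges degree-2 chains (conserving length
   to 1e-9) and prunes dead-end spurs shorter than
   `spur_fraction × toepad_length` (default 2%), along with degenerate
   raster self-loops.
4. **Metric**: `c1` = total perimeter of the domains (the interior faces
   of the planar embedding, found by angular face traversal; an edge
   shared by two domains counts in both) and `c2` = total length of
   incomplete (bridge) edges, both divided by the toepad length — taken as
   the extent of the projected outline along its principal axis, which is
   the only unambiguous desk-scale reading of "length of the toepad".

Samples are compared by Euclidean distance after per-component
normalization with inter-sample mean and standard deviation
(`fit_normalizer()`), so neither component dominates by scale alone.

## Calibration

`bayes_optimize()` is a seeded global minimizer: Latin-hypercube
initialization, a Matern-5/2 Gaussian-process surrogate whose lengthscale
is chosen by marginal likelihood on a small grid, expected-improvement
acquisition over a random candidate sweep with L-BFGS refinement, a
patience-based stopping rule, and an optional final coordinate pattern
search ("polish") that drills into basins narrower than the surrogate's
resolution. Failed simulations (element inversion at extreme parameter
combinations) enter the history at 10 × the worst successful objective, so
the surrogate learns to avoid them without crashing the fit. The two-stage
protocol (`staged_fit()`) first fits the five control parameters, then the
three epidermis parameters against the treated target with dermis values
carried over unchanged.

The calibration tests run at desk scale: a coarse dome (base radius 0.9,
epidermis 0.1, rigid core at depth 0.25, ~10k tetrahedra, ~6 folds) and
less than a hundred objective evaluations, versus thousands of iterations
on full-size meshes in a production fit. At this scale the two-component
metric identifies the epidermal growth well but the modulus only coarsely:
the metric responds to `E_epi` mainly through the fold wavelength
(`∝ E^(1/3)`), a weak signal compared to pattern-rearrangement noise on a
dome that fits only a few folds, which is why the recovery test uses a
mask quantile of 0.55 (where the valley network stays connected and its
metric varies smoothly), a fine raster, and the polish stage aimed at the
exact-match basin around the generating parameters (the deterministic
pipeline returns distance 0 there). Even so, the metric's level sets are
nearly degenerate on such a small pattern: distinct `(E, nu, lambda_T)`
combinations produce fold networks with matching cycle-perimeter and
dead-end totals, so a 30% recovery tolerance on all parameters sits at or
beyond the information limit of the metric at this scale, and the
recovery check can fail for that reason rather than for any defect of the
optimizer. Patterns an order of magnitude richer (larger domes, more
folds) sharpen the objective and restore identifiability, at a
computational cost outside a test suite's scope.

## Nuclei detection and layer densities

EdU+ nuclei appear as bright blobs in a 3D intensity volume. The detector
computes the three principal signal curvatures — eigenvalues of the
negated Hessian of the Gaussian-smoothed volume, so bright blob centres
give all-positive values — and scores voxels with the geometric mean of
the positive parts, `ks = (k1+ k2+ k3+)^(1/3)`, which is zero unless the
signal curves downward in all three directions. Voxels above a threshold
are grouped by 26-connectivity; each component's plain voxel-mean is one
cell. The threshold has no universal scale (it depends on intensity units,
nucleus size and smoothing), so the default is anchored at half the score
of one isolated reference blob rendered at the configured peak intensity
and radius (`calibrate_k_threshold()`). Smoothing defaults to 2 voxels,
about the expected nucleus radius.

Layer densities use the clipped-box estimator: around each sampling point
(a lattice with spacing half a box edge, by default), cells are counted in
an 80-voxel box intersected with the layer and the volume bounds, and
divided by the clipped volume, which makes the estimate unbiased at layer
boundaries. The headline quantity is the percent contrast
`100 (mean_epi − mean_derm) / mean_derm`.

The synthetic generator (`make_edu_volume()`) places Poisson-distributed
Gaussian nuclei in a flat two-layer geometry with independent layer
densities plus Gaussian background noise. Its defaults are the study
conditions: dermal density `5e-5` cells/voxel³, epidermal/dermal ratio
1.23 (the 23% proliferation excess of the untreated E13 epidermis),
nucleus radius 2 voxels, peak/noise ratio 10. The acceptance experiment
uses five 576 × 576 × 256 volumes (about 2,600 epidermal and 2,100 dermal
nuclei each), sized so that Poisson counting noise on the recovered
contrast (±1.6 points, s.d.) sits well inside the ±3-point tolerance. What
the generator does *not* emulate — anisotropic PSFs, attenuation with
depth, intensity inhomogeneity, curved layer boundaries, clustered
divisions — means passing tests certify the estimator and detector, not
robustness to real LSFM artefacts.

## Synthetic geometries and targets

`make_bilayer_slab()` builds structured bilayer slabs (six conforming
tetrahedra per cell, dermis graded coarser away from the interface;
optional side clamping for confined-growth setups). `make_toepad_dome()`
builds a spherical-cap shell: a triangulated disc is lifted onto the cap
and extruded inward along the sphere radius, prisms are split into
conforming tetrahedra by the minimum-vertex-index rule, the epidermis is
always at least two element layers thick, and the dermis–muscle interface
ring is clamped. Element layer labels follow centroid depth from the outer
surface. Mesh resolution is a free knob (`target_edge_length`): no
reference element counts exist for the original embryo meshes.
`make_labyrinth_network()` thresholds difference-of-Gaussian band-passed
noise (power peak at the requested wavelength) and skeletonizes it — a
quick source of target networks with tunable cycle/dead-end mix: at a
threshold quantile of 0.35 the valleys stay mostly tree-like, around 0.5
they percolate into nets with domains.

All generators draw every random number from one explicit seed argument
and restore the caller's RNG state.

## Numerical choices and limitations

- Tolerances: relaxation force tolerance is problem-scaled (dimensionless
  stress units × element size); tests use 1e-5–5e-5. Metric arc lengths
  are conserved exactly by simplification; raster quantization error is
  set by the pixel size (0.8 × median edge by default, finer for
  calibration).
- Tie-breaks: symmetric connected components take exact voxel-mean
  centroids; equal-angle half-edges at a network node are ordered by
  index; buckling symmetry is broken by the seeded perturbation, never by
  floating-point accident.
- Degenerate inputs: empty masks give empty networks (metrics (0,0));
  zero-density volumes give zero centroids; a labyrinth threshold that
  erases the pattern warns and returns an empty network; inverted
  elements and non-convergence raise errors carrying diagnostics, and the
  calibration converts them into penalty objectives.
- The solver is explicit and serial: meshes beyond ~10^5 elements or
  near-incompressible materials want an implicit or mixed-element method,
  deliberately out of scope. Inertial (dynamic) phenomena are not
  modelled; steady states only.
- The fold metric is a 2-vector: patterns with equal cycle perimeter and
  dead-end length are indistinguishable by construction, an intrinsic
  limit inherited by everything downstream of `compute_metrics()`.
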