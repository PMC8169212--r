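---
title: "Methods: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each
stage assumes, which parameters matter, where the design was genuinely
open and what was decided, and what the synthetic data can and cannot
tell you about real tissue.

## The problem

Exchange organs such as the placenta combine two circulations: a
branching, vascularized tissue phase and an open porous blood space
around it. Given a segmented 3D image volume with phases
`0 = pore/IVS`, `1 = tissue`, `2 = vessel lumen` at an isotropic voxel
size, the package quantifies (i) the vessel network's branch geometry,
(ii) the pore space's size, connectivity and percolation structure,
(iii) the tissue-scale flow the pore space supports, (iv) classical 2D
stereology estimates for cross-validation, and (v) how the precision of
any such morphometric depends on the size of the region it is measured
on. Because suitable public volumes of this kind are not generally
available, the package ships a first-class synthetic-data module and
validates every stage against analytic or brute-force oracles.

Axis convention, stated once: arrays are indexed `[z, y, x]`
(`dim = c(nz, ny, nx)`), voxel offsets in arguments are 0-based, and
crops use half-open intervals. Volumes are stored as multipage TIFF
plus a JSON sidecar carrying the voxel size; a file without a sidecar
is refused unless the voxel size is given explicitly.

## Synthetic media

**Boolean medium.** The tissue phase is a union of spheres with Poisson
centers (sampled in a domain padded by the largest radius, so the
medium is stationary up to the boundary) and lognormal radii
(positivity and a right tail; the real villous morphology is not
modelled — only the solid fraction and the correlation-length scale are
emulation targets). For a Poisson process the probability that a voxel
center is covered depends only on the continuous sphere-volume moment,
so the analytic intensity `lambda = -log(1 - phi) / E[V]` is unbiased
and needs no discretization calibration. The generator accepts the
natural Poisson draw whenever its realized fraction is within ±0.01 of
the target and otherwise adjusts the sphere count minimally to the edge
of that tolerance. The tolerance is deliberately not tightened further:
pinning the realized fraction to the target suppresses volume-fraction
variance at ROI scales approaching the domain and visibly distorts the
fluctuation-scaling slope. Rasterization uses the center-inclusion rule
(a voxel belongs to a sphere iff its center is inside), used
consistently by all analytic volume checks.

**Vessel trees.** A recursive bifurcating tree of swept-ball tubes:
per-generation radius decay, mean segment length with ±20 % uniform
jitter, a fixed opening angle at random azimuth, and a smooth
transverse "wiggle" (tapered to zero at the branch ends so children
meet their parents). The generator returns the exact centerline
polylines with per-branch radius, arc length and tortuosity, which is
what makes skeleton-recovery testing possible. Radii below 1.5 voxels
are refused as unresolvable. Defaults (root radius 10 µm decaying by
0.8 per generation, 80 µm segments, 40° branching, at 2 µm voxels)
give capillary-like length-to-diameter ratios around 8 and keep two
bifurcation levels inside a 160³-voxel canvas.

**Grayscale rendering.** Per-phase mean intensities, Gaussian blur and
additive white noise, in that order — enough structure to exercise
segmentation fusion. No X-ray physics, phase-contrast fringes or
reconstruction artifacts are simulated, so fusion results here bound
the *algorithmic* behaviour, not performance on real reconstructions.

## Segmentation fusion

The volume is sliced into stacks parallel to the three coordinate
planes; an injected pure 2D predictor (`matrix -> binary matrix`)
segments each slice; the three reassembled masks are produced for each
of four rotations about the z axis (the fourfold symmetry axis), every
mask is rotated back, and the 12 aligned masks are summed. 90°
rotations on an integer grid are lossless; non-square x–y extents are
zero-padded to square first and un-padded after (the behaviour for
non-cubic volumes is our decision — nothing forces a particular
padding, and it is unit-tested). Agreement thresholds are exposed as
presets: ≥ 6 of 12 for tissue/blood volumes, ≥ 9 of 12 for vessels.
Dice of two empty masks is defined as 1 (identity of empties; the
conservative convention, unit-tested). The test suite verifies the
vote counts against an independent brute-force loop, monotone nesting
of thresholded masks, and that fusing a deliberately noisy predictor
beats its single-view prediction in nearly all random trials — the
rationale for the averaging approach.

## Vessel skeletons

Thinning is sequential border deletion over six directional
sub-iterations; a voxel is deletable only when it is *simple* in the
digital-topology sense (one 26-component of foreground neighbours, one
6-component of background within the 18-neighbourhood reachable from a
face neighbour), so topology is preserved exactly; curve endpoints are
kept. The result is traced into a graph (endpoint / junction
classification by 26-neighbour count, adjacent junction voxels merged
into one node), and free-ended spur branches shorter than 2 voxels are
pruned as thinning artifacts.

Branch metrics: arc length of the moving-average-smoothed polyline
(window 5 voxels; raw lattice paths overestimate length by a few
percent through zig-zag), diameter as twice the Euclidean distance
map at the centerline summarized by the median (robust to junction
inflation), tortuosity as arc length over the endpoint chord. The
distance map treats the domain exterior as background for vessels
(objects are clipped by the domain) but as continuing pore space for
the pore analysis (the medium is stationary); both behaviours are
exposed via `distance_map()`. Tip extension toward the mask boundary
exists as an option but is off by default: the medial axis of a
capsule-ended tube genuinely stops at the cap center, and extension
would overshoot by one radius.

Recovery against the generator is assessed on the skeleton as a *curve*
(`assess_tree_recovery()`): the skeleton points nearest to the true
branch endpoints are joined by the geodesic along the skeleton network.
This is deliberate: where two child tubes overlap near a bifurcation
the rasterized union stays fused for roughly one diameter, so the
skeleton junction sits slightly downstream of the true branch point;
edge-label-based matching would misattribute that shared stub, while
the geodesic measurement is insensitive to it. On twenty random trees,
≥ 95 % of branches with radius ≥ 3 voxels recover diameter within one
voxel, length within 5 % and tortuosity within 0.05; thinner branches
are excluded, mirroring the 3-pixel resolvability cutoff
(`filter_min_diameter()`, 2.43 µm at 0.81 µm voxels).

A directional caveat is asserted rather than hidden: skeletonizing a
2× down-sampled mask degrades diameter accuracy measurably, which is
why whole-network metrics computed on down-sampled data should be
treated as less accurate than single-tree metrics at full resolution.

## Pore networks and percolation

`separate_pores()` computes the Euclidean distance transform of the
pore phase, smooths it (Gaussian, default σ = 2 voxels — the marker
rule is fully specified here because the reference implementations in
commercial tools are not public), takes local maxima with a minimum
peak separation of `max(2, σ)` voxels as markers, and floods the
negated map by a priority queue restricted to the pore phase. Every
pore voxel is assigned to exactly one region (asserted); a small
component that loses its only peak to suppression by a nearby peak in
another component becomes its own region. Region adjacency is
6-connected — a throat is a shared voxel *face*; 26-connectivity would
merge diagonal kisses. Throat diameter is the largest inscribed-sphere
diameter over the interface voxels (consistent with the ball-and-stick
rendering and with bottleneck semantics); throat length is
center-to-center (the alternative, interface-to-interface, is not used
— a documented choice). Media built from overlapping spheres have tiny
isolated pore pockets at grain triple-junctions; `largest_component =
TRUE` restricts the analysis to the connected pore space, which is the
physically meaningful domain for flow and is how the pipeline runs it.

The critical percolation diameter d\* inserts pores and throats in
descending diameter order into a union–find structure (throats pend
until both endpoint pores are active; boundary pores union with a
virtual node) and reports the diameter at which the source first
reaches the boundary. "Central pore" means a uniformly drawn pore whose
center lies in the central eighth of the domain, under the caller's
seed; "periphery" means any domain face. Union–find results are tested
to equal an exhaustive threshold-sweep BFS oracle on random networks,
and d\* is monotone under throat addition.

## Stokes flow and Darcy permeability

The flow problem fixes pressures on the two faces normal to the flow
axis, makes the four lateral faces impermeable (zero normal velocity
with free tangential slip by default; "noslip" is available, and a
wholly obstacle-free domain with slip walls is rejected as ill-posed),
and imposes no-slip on all fluid–solid interfaces via ghost reflection.
Discretization is a marker-and-cell staggered grid: velocities on cell
faces, pressures at fluid cell centers, a 7-point viscous Laplacian per
component with half-control-volume weighting at the pressure-boundary
faces (which keeps the saddle-point system exactly symmetric). Fluid
cells connected to neither pressure face are excluded (their pressure
would float); if no path connects the faces the solver returns a
zero-flux field flagged non-percolating. The system is reduced to its
pressure Schur complement — symmetric positive definite — and solved by
conjugate gradients, with the three per-component viscous blocks
factored once by CHOLMOD sparse Cholesky; the default relative
tolerance is 1e-8 and solutions are linear in the pressure drop by
construction. Default viscosity is 0.003 Pa·s (whole blood); the
default pressure drop scales a 10 Pa/mm physiological-range gradient to
the domain length. Permeability uses the full cross-section (solid
included), `k = QµL/(AΔp)` in µm².

Validation is by closed forms: plane Poiseuille (slab permeability and
the parabolic profile's max/mean → 1.5), Hagen–Poiseuille in a
voxelized cylinder (within 10 % at radius ≥ 8 voxels — the residual is
staircase drag), strict error decrease under grid refinement, exact
linearity, and discrete mass conservation to solver tolerance.

Streamlines integrate the normalized velocity with fixed-step RK4
(0.25 voxel) and per-component trilinear interpolation on the staggered
grids, seeded on inlet-face fluid cells with probability proportional
to the local influx so fast channels are represented in proportion to
the flow they carry. Tortuosity is arc length over endpoint chord;
streamlines shorter than `min_length_um` (default 85 µm, about one
pore: flow within a single pore is effectively straight) are
discarded.

## Direct 3D morphometrics and scale dependence

**Surface area.** S_V is the triangulated area of the 0.5 iso-surface
of the phase indicator over the domain volume. The triangulation is the
tetrahedral variant of marching cubes (each 2×2×2 cell split into the
six Kuhn tetrahedra; identical decomposition in every cell, so faces
match): the same piecewise-linear convergence class without the
256-case table. The indicator is pre-smoothed with a Gaussian of
σ = 0.7 voxels: σ = 0 leaves the midpoint-surface orientation bias
(about +20 % on oblique planes), large σ erodes high-curvature ridges
(−16 % on a sphere-union medium at σ = 1). σ = 0.7 was fixed against
two analytic oracles — a digitized sphere (error ~2 %) and the
closed-form Boolean-model S_V (~10 %) — and the residual plateau is
what the sphere-convergence test measures. The iso-surface lives on the
cell grid, so a planar interface has exactly (n−1)² cell-grid area and
domain faces are never counted.

**ROI fluctuations.** The volume is tiled into non-overlapping ROIs
with square x–y extent and a fixed z thickness (default 243.75 µm
equivalent); per ROI the metric is computed (volume fractions via a
summed-area table, O(1) per ROI); sizes with more than 1000 tiles are
thinned systematically (every n-th tile in (z, y, x) order, seedless).
`n_offsets > 1` adds shifted tilings on an offset grid — repeated
systematic sampling — which stabilizes the sd estimate at sizes where
one tiling yields only a handful of tiles. `fit_scaling_exponent()`
fits log(σ/µ) against log(V_ROI) by least squares above a minimum size
(pass roughly 2λ so the asymptotic regime is fitted) with a bootstrap
CI over the per-size ROI samples.

The headline check reproduces two scale-law numbers on the synthetic
medium (192³ voxels at 2 µm, tissue fraction 0.65, 16 µm mean grain
radius, five seeds — sizes chosen so the λ-scale structure is far
smaller than the domain while the whole computation stays at desk
scale): the fitted slope is −1/2 within ±0.1, and its implied
error-halving volume ratio `2^(1/|slope|)` is 4 within 20 %. The
per-size relative error is the within-seed pooled standard deviation
over three-offset tilings (pooling raw samples across realizations
would add the between-realization mean variance coherently to every
size), and the fit weights each size by its degrees of freedom —
plain sampling-theory choices, made because the largest ROI sizes
admit only a few independent tiles per volume.

**Autocorrelation.** Ĉ(r) = (S₂(r) − φ²)/(φ − φ²) with S₂ estimated by
FFT autocorrelation, zero-padded with exact overlap-count normalization
by default (a periodic estimator is selectable), radially binned at one
voxel. Ĉ(0) = 1 identically. The correlation length λ is the smallest
r with mean Ĉ below 1 %, linearly interpolated between bins. On a
single desk-scale realization Ĉ plateaus at the ±1–3 % sampling level
at large lags, so the 1 % crossing is taken on a seed-averaged mean
curve (which is also what a "mean autocorrelation" threshold denotes);
single-realization curves may legitimately fail to cross, and the
function then raises an error rather than extrapolating.

## Virtual stereology

Point counting places an n×n dot grid (default 11×11) at uniform
fractional positions inside a systematically placed field of view
(centered, with an optional offset — the exact placement rule is our
choice and the unbiasedness test randomizes it); `V_V = P_p/P_n`.
Intercept counting centers horizontal test lines (default 10×10
crosses, 12 µm lines) and counts binary transitions along the sampled
profile at pixel resolution — no sub-pixel interpolation, matching
manual counting granularity; `S_V = 2 I_L`. Horizontal-only lines are
deliberate: on oriented laminates they produce the textbook orientation
bias (up to a factor 2, or zero for boundaries parallel to the lines),
which `compare_2d_3d()` reports rather than corrects — this machinery
is what contextualizes 2D-vs-3D surface-density discrepancies in real
anisotropic tissue.

## Pipeline

`run_pipeline()` executes the stages in dependency order on one
synthetic scene (Boolean medium + embedded tree), writes per-stage
CSV/JSON outputs, a `report.json` aggregating all summaries and a
time-stamp-free manifest, and is byte-identical under a repeated
config+seed (per-stage seeds derive from the global seed by a stable
hash so stages can be rerun independently). The default demo runs a
96³ scene in a few minutes on one CPU. The package deliberately ships
no shell entry point: its users drive it from R, and the functions,
the acceptance script and this vignette are the interface.

## Limitations

- The Boolean medium matches a solid fraction and a correlation-length
  scale, not villous branching morphology, compliance or anisotropy;
  passing tests demonstrate correctness of the estimators, not their
  field performance on real reconstructions.
- The grayscale renderer omits imaging physics; fusion results bound
  algorithmic behaviour only.
- Desk-scale guards: the Stokes solver is intended for grids up to
  roughly 160³ (memory of the sparse factorization grows quickly);
  gigavoxel volumes and out-of-core processing are out of scope, as is
  HDF5/DICOM/NIfTI I/O.
- Skeleton equivalence with proprietary centerline extractors is at the
  level of metrics on fixtures, not voxel-identical skeletons; the
  EDT-based diameter is a documented estimator choice.
- Pore statistics on sphere-union media include, by construction, tiny
  isolated pockets; analyses meant to mirror a connected blood space
  should use `largest_component = TRUE`.
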