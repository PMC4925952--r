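---
title: "Simulating compressive fracture of idealized trabecular bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating compressive fracture of idealized trabecular bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

Age-related bone loss weakens trabecular bone through two microstructural
routes: trabeculae become thinner, and some are resorbed outright. Resorption
can strike random sites or preferentially the trabeculae that carry little
mechanical strain, and it can remove load-aligned (vertical) or cross-bracing
(horizontal) members. Because these routes are confounded in real specimens,
`trabsim` studies them in idealized lattices where each degeneration route can
be applied in isolation at an exactly controlled bone-volume-fraction (BV/TV)
cost, and their mechanical consequences compared by simulating compression to
failure.

## Geometry: ideal rod and plate lattices

Two archetypes are generated as periodic lattices of axis-aligned boxes:

* **rod-like** — a cubic open cell: three orthogonal families of square
  struts crossing at cell centers. The thickness-to-spacing ratio
  `x = t/a` fixes the volume fraction through `BV/TV = 3x^2 - 2x^3`
  (inclusion–exclusion over the three families and their junction cubes);
* **plate-like** — two orthogonal families of vertical walls forming a square
  honeycomb, plus horizontal shelf plates at each cell level:
  `BV/TV = 1 - (1 - x)^3`.

Given a target BV/TV and thickness, `solve_spacing_for_bvtv()` inverts the
closed form by bisection and rounds the spacing to 0.1 µm. The normal rod
model uses 140 µm struts at BV/TV 10.29% (spacing ≈ 705 µm); the normal
plate model 140 µm walls at 27.69% (spacing ≈ 1367 µm).

Voxelization uses *exact partial-occupancy fractions*: every voxel stores the
exact fraction of its volume inside the union of boxes (computed per voxel by
the same inclusion–exclusion). Two consequences matter. First, the voxelized
BV/TV equals the continuous closed form to machine precision, at any voxel
size — there is no staircase bias to correct for. Second, a thickness such as
the aged 126 µm, which is not an integer multiple of the mesh size, is
representable on the same grid as the normal model, so normal and aged models
share one mesh and their comparison is not confounded by remeshing. The voxel
edge is snapped to the nearest value dividing the cell spacing evenly
(requesting 35 µm on the rod lattice gives 35.3 µm), keeping elements cubic
and the grid exactly tiling the domain.

Default extent is 5×5×5 cells for production runs and 3×3×3 (rod) in the test
suite; the published figures do not state the model extent, so it is a free
parameter here, and apparent properties do depend on it mildly.

## Degeneration transforms

All transforms operate on whole struts (node-to-node rod segments, or
wall/shelf panels between junction lines) and are BV/TV-non-increasing:

* **two-step aging** — a degenerated region is selected (uniformly at random,
  or the lowest-strain-energy fraction of struts under a 0.1% elastic
  compression probe; the region fraction defaults to 0.30), thinned to the
  aged thickness (126 µm by default), and then region struts are resorbed
  whole — in seeded random order, or in ascending strain-energy order for
  low-strain degeneration — while the next whole strut still fits under the
  target reduction. The residual gap, smaller than one strut volume, is
  closed by solving a slightly smaller thickness for the remaining region
  struts, so the achieved relative reduction matches the target essentially
  exactly. The thinning/loss split is not quantified in the source data for
  this degeneration sequence; making thinning absorb the targeting residue is
  this package's choice, and it is what makes reductions of 15% (rod) and
  25% (plate) reproducible to well under the ±0.5 percentage-point tolerance.
  If resorption exhausts the region before the target is met, removal
  continues with the next-least-strained struts (resorption progressing
  outward) and, as a last resort, the gap is closed by slight uniform
  thinning of all remaining struts.
* **thinning-only** — one uniform thickness factor for every strut, solved by
  bisection on the exact continuous volume.
* **vertical / horizontal loss** — seeded random removal of whole struts of
  one orientation, stopping at the whole strut landing nearest the target
  (8% by default); the granularity of whole struts limits the precision of
  these two patterns to one strut volume.

Struts touching the loading platens are never resorbed (load-introduction
artifacts); they may be thinned. Fixed seeds make every transform
bit-reproducible.

## Micro-FE model

Solid voxels become 8-node trilinear hexahedra with element modulus
`E × solid_fraction × damage_scale`; 2×2×2 Gauss integration for stiffness and
single-point centroid strain recovery. Compression is displacement-controlled
between frictionless platens: bottom-face nodes fixed in z, top-face nodes
driven in z, lateral motion free, plus three in-plane pins chosen compatible
with uniform Poisson contraction (so a solid block reproduces the uniaxial
closed form exactly). Apparent stress divides the platen reaction by the full
bounding-box cross-section; apparent strain divides platen displacement by
model height. Floating solid not connected to both platens is dropped before
assembly.

The symmetric stiffness is assembled once as a sparsity template plus a
projection matrix from element scales to matrix entries, so damage updates
refill the numeric values in O(nnz). Systems solve by sparse Cholesky
(CHOLMOD); after a damage update the stale factor serves as the
preconditioner for conjugate gradients (relative residual 1e-8), and a full
numeric refactorization happens only when that stalls — the step that makes
softening-phase iteration affordable. A Jacobi-preconditioned CG path exists
for systems past a configurable size threshold.

## Tissue law

The tissue is isotropic (E = 12 GPa, ν = 0.3 for trabecular bone;
E = 1300 MPa for the polyamide-12 replica preset) with asymmetric
principal-strain thresholds: tensile yield/crack initiation at 0.33%/0.61%,
compressive at 0.81%/1.02% (1.5%/10% symmetric for polyamide-12). Between
yield and crack initiation the uniaxial tangent is 5% of E. Beyond crack
initiation the uniaxial stress falls linearly to zero over a strain span
`2 G_f / (σ₀ h)` — crack-band regularization with energy release rate
G_f = 0.33 N/mm, initiation stress σ₀ from the bilinear curve, and element
size h — so the energy dissipated by a one-element-wide band equals G_f per
unit crack area independent of the mesh. The state of an element is its pair
of history-peak tensile and compressive demands (largest/smallest principal
strain at the centroid); the mode with the larger demand-to-yield ratio
governs (ties to tension, whose thresholds are lower), damage is a scalar
acting isotropically on the secant modulus, never heals, and the plane normal
of a newly initiated crack (the dominant principal direction) is recorded for
reporting. A commercial plasticity kernel with asymmetric yield would offer
the same uniaxial response; the damage-secant form reproduces that printed
behavior while unloading to the origin, and is the only part of the response
the study constrains.

Two deliberate simplifications: damage is isotropic even though the crack
normal is recorded (no enriched-crack kinematics — discrete crack enrichment
is out of scope), and cracked elements lose stiffness in compression as well
(no crack-closure recovery).

## Incremental driver

Loading advances in equal apparent-strain increments (default 100 steps to
5%). Within each step the assemble–solve–update loop repeats until no element
changes state; because demands and damage only ratchet, this secant (Picard)
iteration is monotone and converges without a consistent tangent. Damage
evolution is viscously regularized: within an increment `dε` each element
closes only `dε/(dε + τ)` of the gap to its target secant scale
(τ = `viscous_stabilization`, default 1e-4 in apparent-strain units; 0
recovers the inviscid law). This Duvaut–Lions-style relaxation damps the
softening cascades that otherwise let a whole cross-section fail inside a
single increment, the same role the viscous parameters of commercial codes
play. Elements at damage ≥ 0.999 are snapped to fully failed, keep a 1e-5
residual scale for positive definiteness, and are eroded from the load-path
connectivity graph. If more than 5% of elements change state in one increment
(or the iteration budget is hit with the response still moving), the
increment is rolled back and bisected, up to four levels.

A run terminates at the earlier of: load-path disconnection of intact
elements (complete fracture), apparent stress falling below 10% of the
running peak (load drop), the strain limit, or an unresolvable
non-convergence (reported as such, with the history up to that point — the
same behavior the source study reports after complete fracture, with little
effect on the extracted metrics). The fracture strain reported is the
termination strain; the strain at ultimate stress is also recorded
separately, since the two ends of the softening tail are distinct points.

## Analysis

`extract_metrics()` reads each curve: apparent modulus (least squares through
the origin on the first three steps), ultimate stress, strain at ultimate,
fracture strain, and a 0.2%-offset yield point when the curve crosses it.
`ordering_checks()` aggregates replicate seeds by per-model medians and
evaluates the orderings of interest — normal > random-site aged > low-strain
aged; thinning > horizontal loss > vertical loss in residual strength at
matched reduction; plate family > rod family. `fracture_site_proximity()`
measures distances from failed elements to the medial lines/planes of
resorbed struts.

## Problem sizes, tolerances, degenerate inputs

* The test battery runs the rod family at 3×3×3 cells with ~70 µm voxels
  (two elements across a strut) and the plate family at 2×2×3 cells with
  ~137 µm voxels (one element across a wall), three replicate seeds for the
  rod family's stochastic models and a single seed for the plate family's
  (plate runs cost several minutes each), 40–50 increments to 4% strain.
  These sizes keep the full battery at desk scale; they are the package's
  choice of test conditions, not the production defaults. One element across
  a wall resolves membrane action but underresolves wall bending and
  junction strain concentrations, and the plate family fails earlier than it
  would at the production mesh — the plate-family magnitudes in the test
  suite inherit that bias (see Limitations).
* Geometry targeting: BV/TV inversion to 1e-3 absolute before rounding;
  two-step reduction targeting is exact to bisection tolerance (1e-12 on the
  thickness factor); pure-loss patterns are exact to one strut volume.
* The elastic solve enforces a 1e-8 relative residual; secant iteration stops
  at 1e-5 maximum scale change (1e-8 in the energy oracles).
* Degenerate inputs: zero target reduction is the identity; an empty or
  disconnected model raises before assembly; `spacing = thickness` produces
  the fully solid block; zero applied strain returns a zero field.

## What the generator emulates, and what passing tests do not show

The lattices reproduce controlled BV/TV, strut thickness, orientation classes
and connectivity — the variables the degeneration study manipulates. They do
not reproduce the irregular architecture of real trabecular bone: curved and
oblique trabeculae, thickness variation, marrow-space heterogeneity,
plate–rod mixtures, or tissue-level heterogeneity and anisotropy. Passing
tests therefore demonstrate the mechanics of the idealized system, not
predictions for any real specimen. Within the simulation itself, geometric
nonlinearity is absent: slender-strut buckling and P–delta amplification —
mechanisms the literature implicates when low-strain cross-braces are lost —
cannot contribute here, so ordering comparisons that hinge on them
(particularly random-site vs low-strain-site loss) probe only the
redistribution-of-load mechanism that linear kinematics retains.

## Known limitations

* Smeared, isotropic continuum damage with element erosion replaces discrete
  crack enrichment; crack paths are band-like and the recorded crack normals
  are diagnostic only.
* The crack band calibration is uniaxial; a band whose Poisson contraction is
  confined by stiff neighbours dissipates up to ~35% more than G_f (the
  oedometric factor at ν = 0.3). The energy oracle therefore isolates the law
  at ν = 0.
* Fracture strains depend visibly on mesh resolution at coarse meshes (the
  rod model moves from 1.55% to 2.0% fracture strain between 70 µm and 35 µm
  voxels); family-internal comparisons are run at matched mesh for this
  reason.
* No rate dependence, fatigue, or load-reversal stiffness recovery; no
  contact; platens are frictionless by assumption.
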