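---
title: "Strain-energy fracture risk assessment of the proximal femur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-energy fracture risk assessment of the proximal femur}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femfri)
```

## The model and its assumptions

`femfri` estimates hip fracture risk as a ratio of energies.  Bone failure
has two faces: cortical bone cracks when local stresses are too high, while
cancellous (trabecular) bone fails by buckling and large deformation — a
strain-driven mechanism.  A strain-energy criterion combines both, because
the strain-energy density `½ σᵀε` grows with stress and strain together.
For each clinically critical cross-section the package integrates the
load-induced strain-energy density over the section to get `U`, integrates
the yield energy density `σ_Y²/(2E)` (the most a material point can store
before yielding) to get `U_Y`, and reports the fracture risk index
`η = U/U_Y`.  A section with `η > 1` cannot absorb the imposed energy
elastically and may fracture.

The mechanical model is deliberately the simplest one consistent with this
question:

* **Linear elastostatics.** Small strains, no contact, no post-yield
  redistribution, no dynamics.  The impact force of a sideways fall enters
  through a quasi-static peak-force model, not a transient simulation.
* **Isotropic, inhomogeneous material.** Each element's Hounsfield value
  maps to ash density (`ρ = 0.04162 + 0.000854·HU` g/cm³) and then to
  `E = 10500·ρ^2.29` MPa and `σ_Y = 116·ρ^2.03` MPa with a constant Poisson
  ratio ν = 0.4.  Bone anisotropy and separate tension/compression yield
  are out of scope.
* **4-node linear tetrahedra.** Strain is constant per element, so every
  recovered field (stress, energy density, von Mises measures) is
  piecewise constant.  This matches the element used in the original
  workflow and keeps the section quadrature semantics simple.

Units are mm–N–MPa throughout: 1 MPa = 1 N/mm², energies in N·mm.

### Units of the section energies

The section integrals apply a 2D quadrature to a *volumetric* energy
density, so `U` and `U_Y` carry units of energy per unit thickness
(N·mm/mm).  The thickness factor is common to numerator and denominator and
cancels in `η`; the quantities are documented as-is rather than rescaled.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `nBins` | 50 | – | material bins; femur displacement solutions converge above ~50 bins |
| `nu` | 0.4 | – | constant Poisson ratio for bone |
| `targetEdgeLength` | 8 | mm | tet edge bound; displacements converge below ~8 mm |
| `sectionMaxEdge` | 5 | mm | section triangle bound; η converges below ~5 mm |
| `quadratureN` | 3 | – | 3-point (degree-2) rule; the 7-point (degree-5) rule is available for verification and changes η by ~1% |
| `bodyWeightN`, `heightCm` | 700, 170 | N, cm | generic adult subject for phantom studies |
| `headCapture` | 1.05 | ×head radius | head contact-patch capture |
| `trochCapture` | 12 | mm | impact patch radius on the greater trochanter |
| `distalTol` | 5 | mm | thickness of the fully fixed distal band |

Material binning is performed on ash density (the physical variable entering
the power laws) with equal-width intervals, and each bin is represented by
the *mean* density of its members, which preserves the mean stiffness; the
binning rule is otherwise unconstrained by the source workflow.

## The synthetic phantom

No clinical scans ship with the package; every downstream stage is exercised
on a parametric proximal-femur phantom: a shaft cylinder (radius 14 mm,
length 100 mm), an angled neck cylinder (radius 15 mm, length 50 mm, default
neck-shaft angle 130°) with a mild Gaussian isthmus (2 mm deep) so a
smallest-neck section exists in the interior, a spherical head (radius
24 mm), and a cancellous-filled greater-trochanter bulge (radius 15 mm)
lateral of the junction.  A cortical shell of uniform 3 mm thickness at
1200 HU surrounds a cancellous interior at 150 HU (inside the usual 200–2000
and 100–200 HU segmentation windows); Gaussian HU noise (sd 20, clamped at
1 HU) emulates imaging noise.  The greater-trochanter landmark is placed
where the neck-axis extension exits the lateral surface — the sideways-fall
impact point sits opposite the femoral head, which is what makes falls load
the neck.

Meshing classifies a Kuhn-subdivided background cube grid against the
implicit union of these primitives and projects boundary nodes onto the
zero level set.  The grid spacing is `targetEdgeLength/(√3 + 0.8)` and the
projection is capped at 0.4 grid spacings, which together guarantee the
requested maximum edge length; projections that would invert a tetrahedron
are rolled back.  Summed element volumes agree with a Monte Carlo
integration of the implicit solid to well under 2 % at the default edge
length.

What the phantom does *not* emulate: cortical thinning at the neck, the
anisotropic trabecular architecture, realistic periosteal geometry
(calcar, fovea, curvature of the shaft), and osteoporotic density
distributions.  Passing tests therefore demonstrate correctness of the
machinery — calibration laws, solver, anatomy, quadrature — not clinical
validity on real femora.  One consequence worth knowing: on the phantom the
stance-to-fall ratio of the neck η is about 0.5, whereas clinical cohorts
show ~0.1; the short shaft segment makes the stance case bending-dominated
and the uniform 3 mm shell makes the phantom neck comparatively strong.
The *orderings* (fall > stance at neck and intertrochanteric sections,
subtrochanteric safest under fall, stance > fall subtrochanterically) match
the clinical pattern.

## Numerical choices

* **Linear solver.** Sparse Cholesky on the reduced system; when the fall
  case adds single-direction head constraints, they enter as Lagrange
  multipliers and the saddle system is solved by sparse LU.  Solutions are
  deterministic; a relative-residual guard at 1e-8 turns near-singular
  systems into errors instead of garbage.
* **Clapeyron check.** `totalStrainEnergy` equals `½ fᵀd` identically for
  the discrete system; the test suite asserts agreement to 1e-6 relative on
  every solved case.
* **Plane slicing.** A cutting plane is nudged along its normal (by a few
  nanometres) until no mesh node lies on it, so every cut tetrahedron
  yields a clean 3- or 4-gon.  Crossing points are computed canonically
  from the sorted node pair of each edge, so shared faces produce
  bit-identical vertices in both incident tetrahedra; slice boundaries are
  the polygon edges seen exactly once.
* **Section triangulation.** Two constructions: `align = "boundary"`
  (default) ear-clips the exact slice boundary — with interior voids
  bridge-spliced into the outer contour — and refines by uniform 4-splits
  to the requested edge bound; triangles straddle tetrahedra, and each
  integration point is attributed to the tetrahedron with the largest
  minimum barycentric coordinate (nearest tet on ties, lowest index for
  determinism, tolerance −1e-9).  `align = "tets"` fan-triangulates the
  per-tetrahedron slice polygons so each triangle lies in a single known
  tetrahedron; quadrature of the piecewise-constant densities is then
  exactly the area-weighted sum, which is the configuration used to verify
  the quadrature machinery to 1e-12 against a brute-force oracle.  In both
  modes triangle areas sum to the section area to 1e-6 relative (the ear
  clipper verifies its partition exactly and fails loudly otherwise).
* **Quadrature rules.** The standard symmetric degree-2 3-point rule
  (permutations of (2/3, 1/6, 1/6), weights 1/6) and degree-5 7-point rule
  (centroid 9/80 plus the two √15 orbits).  Energy densities are evaluated
  from the containing element, i.e. per-element rather than interpolated
  sub-element — with constant-strain tetrahedra there is nothing finer to
  interpolate.
* **Degenerate inputs.** Nonpositive element volumes, empty node captures,
  planes that miss the mesh, coplanar sphere fits, zero-spread axis fits
  and unsupported quadrature orders all raise descriptive errors; a plane
  tangent to the surface returns zero area with a warning.

## Design decisions in open territory

* **Fall impact direction** is taken perpendicular to the shaft axis within
  the neck–shaft plane, pointing medially; whether the original impact
  vector lay in the frontal plane is not determinable, so the convention is
  explicit and the capture radii are configurable.
* **Neck/trochanteric search bounds** for the section sweeps are fractions
  (0.5–0.95 and 0.95–1.35) of the head-centre-to-junction distance along
  the neck axis, with a 1 mm station step (the usual CT slice thickness);
  the anatomical extent of the "neck region" is a modelling choice, so the
  bounds are parameters rather than constants.
* **Axis fitting.** The proprietary ruled-surface fit is replaced by
  principal-direction fits; for the full anatomy pipeline the neck axis is
  anchored at the fitted head centre and refined through area-weighted
  section centroids, which is insensitive to the faceted phantom surface
  (angle recovery within ~0.3° across 110–140°, asserted within 2°).
* **Equal per-node force split** over the capture sets (not consistent
  surface tractions), as in the nodal-force application being reproduced;
  validation fixtures use tributary-area weighting so the closed-form bar
  solution is reproduced exactly.
* **Equivalent strain** uses the principal-strain form scaled by
  1/(1 + ν′) with ν′ = 0.4, the usual postprocessor convention when no
  formula is stated.

## Problem sizes

The shipped tests run the standard phantom at the converged 8 mm edge
(~28k tetrahedra, ~18k DOF) for the acceptance checks, a 12 mm phantom for
pipeline plumbing, and mesh-edge sweeps over {12, 10, 8} mm with bin sweeps
over {5, 50, 500}; these sizes keep the full suite under a few minutes on a
single core while still exhibiting the convergence behaviour they assert.

## Known limitations

Beyond the phantom realism noted above: no geometric or material
nonlinearity, no dynamic impact, no DICOM ingestion (meshes arrive as
legacy VTK or CSV tables), holes in a cross-section are supported but
nested islands-within-holes are not, and cohort-level statistics are out of
scope — the unit of analysis is one femur under one load case.
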