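---
title: "Predicting knee soft-tissue geometry from corresponded bone meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting knee soft-tissue geometry from corresponded bone meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneemorph)
```

## The modeling problem

Subject-specific musculoskeletal models of the knee need cartilage layers,
menisci, ligaments and cruciate ligaments, but routine imaging and
statistical shape modeling typically deliver only bone surfaces. This
package predicts the soft tissues from corresponded bone meshes — meshes of
the same bone that share vertex count and ordering across subjects, so that
vertex `i` marks the same anatomical location in everyone. Correspondence is
assumed as an input (it is the product of statistical-shape-model based
segmentation, which this package deliberately does not reimplement); it is
what makes three simple mechanisms work:

1. **Index-based landmark transfer.** Attachment sites, meniscal roots and
   measurement landmarks are annotated once, as vertex-index groups on a
   template, and transfer to any case by pure index lookup
   (`transfer_landmarks()`), with no registration at prediction time.
2. **Per-vertex cartilage thickness maps.** On each training case, cartilage
   thickness at a bone vertex is the distance from that vertex to the
   cartilage surface along the vertex normal (`compute_thickness()`). Maps
   live on the shared vertex indexing, so they can be averaged per vertex
   across a cohort, scaled, and projected onto a new bone
   (`predict_cartilage()`).
3. **Elastic wrapping.** Menisci, ligaments, the patellar tendon and
   cruciates are paths, bands, sleeves or tubes that minimize a discrete
   elastic energy while being kept outside the bone + cartilage surfaces
   built so far (`wrap_chain()`, `wrap_membrane()`).

The full pipeline (`build_knee_model()`) runs in a fixed dependency order —
cartilage, menisci, ligament bands and the patellar tendon, ACL, PCL — with
each stage's output appended to the obstacle set of the later stages. The
ACL-before-PCL order matters: the PCL is wrapped around the finished ACL
tube.

## Cartilage thickness maps

For a region of articular vertices, thickness is measured by casting a ray
from each bone vertex along its angle-weighted vertex normal and taking the
first intersection with the cartilage surface; rays that miss within a
50 mm cutoff fall back to the distance to the corresponding cartilage
vertex, and inward (negative) measurements clamp to zero — cartilage cannot
lie inside bone. Region *edge* vertices (those with a neighbour outside the
region) are sealed to zero thickness so the projected surface attaches
smoothly to the bone.

Cartilage thickness correlates with skeletal size, so maps are normalized
by femoral length — the distance between two designated length landmarks —
before averaging: each case's values are multiplied by
`mean_length / case_length`, averaged per vertex, and the mean map is
rescaled by `target_length / mean_length` at prediction time. We normalize
*before* averaging (rather than averaging raw maps and scaling afterwards)
because it makes the mean independent of which cases happened to be large;
for cohorts whose size range is modest the two orders differ negligibly.
Scaling is linear in the length ratio — the minimal model consistent with a
proportional size effect — and is isolated in one place so a different
allometry could be substituted.

Validation is value-space: a predicted map is compared with a measured map
vertex by vertex, and the absolute differences feed the same RMSE / ASD /
HD summaries used for surfaces. For a cohort of `n` cases with independent
per-vertex measurement noise of standard deviation σ, predicting each case
by the mean of the other `n − 1` gives a leave-one-out RMSE of
σ·√(n/(n−1)); the test suite and the acceptance script check this closed
form at n = 20, σ = 0.1 mm.

## The wrap engine

All wrapped structures share one engine. A chain (or a grid of chains) of
nodes connects fixed anchors; the discrete elastic energy is the sum of
squared segment lengths; each relaxation sweep moves interior nodes toward
the mean of their neighbours and then projects any node violating an
obstacle constraint back to the closest admissible point. A node's
constraint is `signed_distance ≥ inflation + offset`, where the inflation
is a property of the obstacle surface and the offset a property of the node
(zero for plain wrapping, half the local meniscal height for meniscal
paths, the minimal cruciate offset for cruciate centerlines).

Numerical choices, all configurable through `wrap_params()`:

* **Gauss–Seidel successive over-relaxation** (ω = 1.5 by default). A
  single-node update with ω < 2 strictly decreases the chain energy, and
  sequential sweeps converge in O(n) iterations, versus O(n²) for
  simultaneous (Jacobi) under-relaxed updates, which at the default
  tolerance would exhaust the iteration cap on a 200-node chain long before
  converging.
* **Monotone energy by construction.** A sweep (relaxation plus projection)
  is accepted only if the total energy does not increase; otherwise ω is
  halved and the sweep retried. When even a tiny step cannot lower the
  energy the chain is at its constrained optimum and iteration stops. The
  recorded energy trace is therefore non-increasing, which the tests assert
  on every wrap.
* **Convergence** at a maximum per-node displacement below 1e-4 mm, capped
  at 10,000 sweeps; non-convergence returns the flagged result with a
  warning rather than an error.
* **Initialization** is the straight chord (or ruled surface) between the
  anchors, lifted out of the obstacles by projection before the first
  sweep.
* **Inside/outside decisions** during relaxation use signed distances from
  a BVH-accelerated closest-point query with angle-weighted pseudonormals.
  Pseudonormals of locally degenerate geometry (e.g. a solid whose
  attachment end has been flattened onto the bone) can flip the sign of a
  far query, so any "deep inside" verdict is verified against the
  generalized winding number, which is immune to local degeneracy. All
  user-facing penetration *verification* (`is_inside()`,
  `max_penetration_depth()`, `meshes_intersect()`) uses the winding number
  directly.
* Anchors are fixed and never projected. They may legitimately lie *on* an
  obstacle surface (meniscal roots on the tibial plateau, ligament
  attachments on the bone) even when interior nodes carry a positive
  offset; only an anchor strictly inside an obstacle is an error.

On a sphere of radius 10 mm with anchors a quarter-turn apart, the
converged 200-node chain reproduces the great-circle length within 0.2%.

One honest limitation: constraints act on nodes, not on the segments
between them. A chain whose anchors are placed exactly symmetrically about
an obstacle can converge with consecutive nodes on opposite sides and the
connecting segment passing through the forbidden zone. Any asymmetry
resolves the ambiguity toward proper draping; anatomical attachment
geometry is never exactly symmetric, but the node-wise nature of the
guarantee should be kept in mind when interpreting clearances.

## Menisci

A meniscus is built in three steps. First, an elastic path is wrapped from
the anterior to the posterior root with a per-node offset of half the local
meniscal height, which forces the path around the femoral condyle while
clearing bone and cartilage. Second, at stations along the path, triangular
cross-sections are erected — a thick outer edge of the local height at the
node, tapering over the local width toward the meniscal center — and
interconnected into a closed wedge mesh. Third, any mesh vertex found
penetrating the composite surface is projected back onto it, so the wedge
adapts to fit between the cartilage layers. Height and width along the
course come from polynomial profiles of measurement data versus relative
outer length (normalized cumulative chord length, 0 at the anterior root).

The meniscal center defaults to the arc-length-weighted centroid of the
wrapped path projected onto its best-fit plane, whose normal also provides
the wedge's "up" direction; an explicit center (and up direction) can be
supplied for degenerate, near-straight paths or custom definitions. The
wedge is a single fixed geometry: meniscal motion with knee flexion is out
of scope.

## Ligaments and the patellar tendon

Each ligament band runs between two attachment areas delineated as vertex
groups. The areas are reduced to matched open curves (best-fit-plane
projection, principal-axis ordering, spline resampling), and one elastic
fibre chain per curve sample is wrapped from origin to insertion. The
fibres are relaxed *independently* — the band is a family of elastic line
segments, interconnected into a flat mesh only afterwards — because
zero-rest-length cross springs would contract the free band edges toward
the middle (the discrete minimal-surface pathology). The generic
`wrap_membrane()` retains cross springs (weight 1 by default) for uses
where a true membrane is wanted.

Volume is added by extruding the relaxed midsurface symmetrically by half
the ligament-specific thickness along its normals and closing the side
walls. Interior fibre nodes keep a clearance of half the thickness during
wrapping so the extruded solid clears the obstacles; solid vertices at the
attachment ends, which legitimately reach the bone, are projected back
onto the obstacle surface. Mid-substance thicknesses are fixed per
ligament (MPFL 2.90, LPFL 1.80, both sMCL bundles 2.10, LCL 2.20, ALL
1.50, POL 1.00, OPL 1.44 mm); the table is data, not geometry, and can be
overridden per call. One thickness serves both sMCL bundles since the
literature value is reported for the ligament as a whole.

The patellar tendon is the exception: closed splines are fitted on the
origin and insertion vertex loops, both are resampled at matched arc-length
parameters starting from the most medial point and travelling in matched
directions, and corresponding points are connected by wrapped fibres. The
resulting closed sleeve *is* the tendon — its thickness is inherent to the
vertex positions, never an assigned value. The sleeve is open at its ends
(it terminates on the attachment rims), so it is the one structure that
cannot serve as a winding-number obstacle downstream; it is skipped when
the obstacle set is extended.

## Cruciate ligaments

A cruciate centerline is a chain of 15 spring elements (16 nodes) from
origin to insertion, relaxed under a constant minimal offset from every
obstacle. The offset default is the structure's mean profile *width*
(twice the mean radius of its radius profile) — enough that the tube
fitted around the centerline clears the obstacles with margin. Around the
converged centerline a tube is built from Frenet–Serret frames: tangents
by central differences, Frenet normals where local curvature exceeds
1e-6/mm, rotation-minimizing (double-reflection) transport on straight
stretches where the Frenet frame is undefined. Radii come from the
polynomial radius profile (degree 2 for the ACL, 4 for the PCL, from the
degree-selection procedure below) evaluated at the nodes and floored at
0.1 mm.

The ACL is built first and its tube joins the obstacle set for the PCL, so
the PCL wraps around the ACL on its course. Because a tube mesh is a
polygonal approximation, its ring polygon is inscribed in the ideal circle
by a factor cos(π/n); when a tube becomes an obstacle its surface is
inflated by `r_max · (1 − cos(π/n))` so clearance guarantees refer to the
ideal round tube. Tube end rings around the attachment anchors lie half
inside the bone (the anchor sits on the surface); those vertices are
projected back onto the obstacle surface, mirroring the ligament
treatment.

## Polynomial profiles and degree selection

Meniscal height and width versus relative outer length, and cruciate
radius versus relative course, are least-squares polynomials. Fitting uses
an orthogonal polynomial basis internally; ordinary power-basis
coefficients are recovered through a Chebyshev-node interpolation solve and
reported for degrees up to 12 (beyond that the power basis is numerically
meaningless on [0, 1] and only the evaluable fit is kept).

The degree is chosen by a sensitivity analysis against an intentionally
over-fitted reference: a 20th-degree polynomial standing in for ground
truth. For each candidate degree the RMSE between its fit and the
reference is computed on a dense 1000-point grid; the curve of RMSE versus
degree flattens at the generating degree, and the selected degree is the
last one whose incremental improvement still exceeds 5% of the degree-0
RMSE (the threshold is exposed as `improvement_tol`). A fit already
indistinguishable from the reference (RMSE below an absolute floor of
1e-9 relative to the data scale) wins immediately, which resolves the
noiseless-constant corner case. On synthetic profiles of generating
degrees 0, 1, 4 and 6 with noise at 1% of the profile range, the procedure
recovers the generating degree in at least 95 of 100 seeded replicates —
in practice all 100.

## Validation machinery

`compare_points_to_surface()` measures, for every reference point, the
distance to the nearest predicted point or surface, and summarizes with
RMSE (root of the mean squared distance), ASD (mean distance) and HD
(maximum distance); `asd ≤ rmse ≤ hd` always, by the power-mean
inequality. The comparison is one-directional (reference against
prediction) by default, with a symmetric option; HD is likewise the
one-directional maximum by default. `leave_one_out()` is a generic driver:
builder, predictor and comparator callbacks, pooled medians and ranges per
metric. `pointwise_error_map()` averages corresponded per-vertex error
magnitudes across cases for rendering.

## The synthetic cohort

Real cohort data are not distributable, so every pipeline stage is
exercised on a deterministic synthetic knee. All three bones derive from
one subdivided icosahedron, so correspondence across cases is exact by
construction: the distal femur is a sphere with two blended condylar
lobes, the proximal tibia a flattened plate with two shallow concave
plateau dimples, the patella a small anterior lens. Geometry amplitudes
are at anatomical scale (condyle radius ≈ 25 mm, cartilage ≈ 2–3 mm,
meniscal heights 4–7 mm) so tolerances transfer to real data. Each case is
the template under a uniform scale drawn from [0.92, 1.08] (emulating
femoral-length variation); cartilage meshes displace the bone by the
scaled ground-truth field along vertex normals; measured thickness maps
add i.i.d. Gaussian vertex noise (σ = 0.1 mm by default) clamped at zero;
profile samples add noise to fixed truth polynomials built from shifted
Chebyshev terms with geometrically decaying weights, so every order up to
the generating degree contributes a visible share. Per-case RNG streams
derive from (seed, case index): extending a cohort never perturbs earlier
cases.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: anatomical shape variation beyond uniform
scale, correspondence error from segmentation, spatially correlated
measurement noise, cartilage loss patterns, and any pathology. The
synthetic cohort validates the *machinery* (exactness, invariances,
closed-form error behaviour, penetration guarantees, determinism), not
clinical accuracy.

Default problem sizes — subdivision-3 meshes (642 vertices per bone),
60-node meniscal paths, 20 × 30 ligament grids, 16-node cruciate chains —
were chosen so a full model builds in seconds while keeping facet error
well below the geometric tolerances being tested; all are arguments.

## Known limitations

* Node-wise obstacle constraints (see the wrap engine note): segment
  midpoints can approach obstacles closer than their endpoint nodes by the
  chordal sag, and perfectly symmetric crossings can thread between nodes.
* The menisci are static; flexed-knee positioning is out of scope.
* Ligament solids near strongly curved attachments can acquire flattened
  cells from the final projection; they remain watertight and
  non-penetrating, but local thickness there deviates from the nominal
  value.
* STL input is vertex-merged by coordinate rounding and is not
  correspondence-safe; PLY is the preferred interchange format.
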