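---
title: "Diaphyseal cross-sectional geometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diaphyseal cross-sectional geometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of what it computes, the
conventions it fixes where the field admits several, and what its green
tests do and do not establish.

## The procedure

The unit of analysis is a *specimen*: a watertight triangle mesh of a
femur-like bone (millimetres), three anatomical landmarks (superior femoral
neck point, medial and lateral distal condyle points) and a group label
(healthy or osteoporosis). Processing is strictly ordered:

1. **Clean** — duplicate/degenerate face removal, largest-component
   selection (isolated piece removal), fan triangulation of boundary holes.
   Non-manifold edges and self-intersections are *rejected with an error*,
   not repaired: meshes exported from segmentation software rarely exhibit
   them, and a faithful repair is a project of its own. This is a
   deliberate simplification.
2. **Decimate** — quadric-error edge collapse to a consistent complexity of
   20,000 faces (default), with a link-condition guard (manifoldness) and a
   triangle-flip guard. Collapse removes two faces at a time on a closed
   surface, so the exact target is reachable whenever the difference is
   even; inputs at or below the target pass through unchanged (logged). A
   result that misses the target or breaks watertightness is an error — the
   documented retry policy is "none": fix or regenerate the input.
3. **Orient** — rigid landmark-based frame construction (Gram–Schmidt): the
   condyle-midpoint-to-neck axis becomes +z (proximal up), the component of
   the medial-to-lateral condyle direction orthogonal to it becomes +x
   (mediolateral), +y is anteroposterior, and the condyle midpoint goes to
   the origin. Inertia-axis orientation was the considered alternative;
   landmarks were chosen because the biomechanical-length convention is
   itself landmark-based, so the two stay consistent.
4. **Section** — 60 planes, evenly spaced over 20–80% of biomechanical
   length (BL = mean neck-to-condyle distance). The distal origin of the
   percent scale is the condyle midpoint projected on the long axis; this
   is an interpretation (the origin is rarely stated explicitly in
   protocols) and is fixed and logged. Each plane–mesh intersection is
   chained into closed loops using exact mesh-edge identity, so loop
   closure cannot be defeated by floating-point coordinate mismatches.
   The largest loop is the periosteal contour, the largest loop nested in
   it the endosteal contour; loops under 1% of the periosteal area are
   discarded as mesh noise (counted and logged). Fewer than two substantive
   loops ("no medullary cavity") or more than two (ambiguity) are errors.
5. **Semilandmarks** — 21 rays per section at angles `2πk/21` from +x,
   originating at the *medullary* (endosteal) centroid. Per ray, the
   endosteal semilandmark is the nearest crossing and the periosteal
   semilandmark the farthest, so the pair spans the full cortical wall even
   when the cortex is locally non-convex; this is one of several defensible
   conventions and is fixed here. Radial thickness is the distance between
   the paired semilandmarks.
6. **Properties** — areas, perimeters, thickness statistics, centroidal and
   principal second moments, chord lengths and section moduli, computed
   from the *full extracted contours* (the semilandmarks feed thickness
   only). Full contours minimize discretization error; a
   `use_semilandmarks = TRUE` switch rebuilds the section from the
   21-point polygons for sensitivity analysis.

## Conventions that matter

- **Moment reference point.** All second moments are about the
  cortical-region *area centroid* with axes parallel to x/y — the standard
  beam-theory choice, and the only one for which `Imin`/`Imax` are true
  principal values. The medullary centroid is used *only* as the
  semilandmark ray origin. Both points are reported.
- **Principal-moment radical.** The implemented identity is
  `√(((Iy−Ix)/2)² + Ixy²)` (equivalently `½√((Iy−Ix)² + (2Ixy)²)`), the
  eigenvalue form of the 2-D inertia tensor, verified in the tests against
  a rotation-scan oracle. Printed variants of this formula sometimes carry
  a `(4Ixy)²` term, which is not the tensor identity; it is treated here as
  a transcription artifact.
- **Theta.** `θ = ½·atan2(2Ixy, Iy−Ix)`, using the two-argument
  arctangent to avoid quadrant ambiguity, then folded into `(−π/4, π/4]`.
  Folding by 90° steps is harmless — any `θ + kπ/2` zeroes the cross
  moment — and makes θ read as "tilt of the nearest principal axis from
  anatomical alignment". Isotropic sections (`Ix = Iy`, `Ixy = 0`) report
  θ = 0 by convention. Note θ is intrinsically ill-conditioned for nearly
  circular sections: the principal direction of a circle is arbitrary.
  Consequently `Zmin`/`Zmax` (which depend on θ through the rotated chord
  lengths) are only meaningfully rigid-invariant on non-circular sections;
  the invariance tests use elliptical phantoms for exactly this reason.
- **Modulus pairing.** `Zmin = Imin/dxθ` and `Zmax = Imax/dyθ` follow the
  literal published pairing; conventions differ across the literature on
  whether the major axis is rotated to x′ or y′, and this choice is flagged
  rather than silently harmonized.
- **Semilandmark accounting.** "1260 semilandmarks per specimen" equals
  60 × 21, i.e. one contour surface. This package counts both surfaces
  (2520 total) but defines the reported statistic per contour surface to
  match the conventional arithmetic.

## The synthetic generator

`synthetic_bone_spec()` describes a tubular diaphysis whose cross-sections
are concentric, axis-aligned elliptical annuli with smoothly tapering
semi-axis profiles. Defaults are chosen to be anatomically plausible for an
adult femur: BL = 420 mm, mid-shaft periosteal semi-axes 14 × 13 mm
flaring ~30–35% toward the metaphyses, endosteal semi-axes at 62% of the
periosteal ones (mid-shaft cortical thickness ≈ 5 mm, cortical area
≈ 350 mm²). The tube spans 5–95% BL so the flat annular end caps sit well
outside the 20–80% sampling range and can never contaminate a sampled
section. Landmarks are synthesized as three points that *encode the
requested biomechanical length exactly* (condyles 50 mm apart at z = 0,
neck on the +z axis); no neck or condyle geometry is modelled, because
downstream processing consumes only landmark distances.

Two osteoporosis modes:

- `uniform_endosteal_expansion` multiplies both endosteal semi-axes by
  `f ≥ 1`, leaving the periosteal surface untouched — the classic
  endosteal-resorption picture. Closed-form ground truth for every
  quantity is retained. `expansion_for_ca_ratio()` inverts the annulus
  algebra so a cohort can be *constructed* with a stated cortical-area
  ratio (default 0.70), constant across levels because the default
  profiles are proportional.
- `regional_thinning` pushes the endosteal boundary outward by a fraction
  of the local cortical thickness, weighted by
  `w(φ) = max(0, sin φ)² + max(0, cos φ)²` (1 on the anterior +y and
  lateral +x directions, 0 in the posterior-medial quadrant) and a
  raised-cosine bump over 20–45% BL. The section is then no longer
  elliptical, so only per-ray thickness truth exists; asking for moment
  truth is an explicit "no closed form" error.

Cohorts add independent per-specimen *lognormal* scale jitter
(`sdlog = variation`, default 0.05 ≈ a 5% coefficient of variation, a
plausible between-individual size spread) — lognormal keeps every radius
positive by construction. All osteoporotic specimens share one expansion
factor.

What the generator does *not* emulate: anatomical curvature of the shaft,
condyle/neck/trochanter geometry, non-elliptical cortical drift,
trabecular bone, segmentation noise, or CT partial-volume effects. A green
pipeline test therefore establishes geometric correctness of the
algorithms, not robustness to real segmentation artifacts.

## Numerical choices

- **Plane nudge.** A section plane passing within 1e-9·(z-range) of a mesh
  vertex is nudged off it, avoiding degenerate point contacts.
- **Ray windows.** Ray–edge intersection uses a half-open edge window
  widened by 1e-9 so a ray through a shared contour vertex is never lost to
  rounding; duplicate hits are harmless because only the nearest/farthest
  crossings are consumed.
- **Ellipse perimeter truth** uses Ramanujan's second approximation,
  relative error below `3h⁵/2¹⁷` (≈ 4·10⁻¹⁰ at a 2:1 axis ratio), exact
  for circles — far below the mesh faceting error it is compared against.
- **STL welding** merges per-triangle vertices after rounding to 1e-6 mm;
  binary/ASCII dialects are auto-detected by the record-size identity.
- **Degenerate statistics.** When both groups have zero within-group
  variance the two-sample tests are undefined; the comparison reports
  p = 1 if the means coincide (perfect null) and p = 0 otherwise (perfect
  separation), with the degeneracy named in `test_name`.
- **Statistical defaults.** The comparison test and α are not canonical in
  this literature; defaults are Welch's t at α = 0.05 with Mann–Whitney as
  an option, no multiple-testing correction by default (per-location
  significance is conventionally reported unadjusted), and a
  Benjamini–Hochberg switch for those who want it. Output names the test
  exactly.
- **Sector convention.** Anatomical quadrants for regional contrasts use
  the left-femur frame: lateral = ±45° about +x, anterior = ±45° about +y,
  etc.; configurable, and documented in the output.

## What the tests establish

- Exact polygon moments agree with closed forms on polygonized annuli to
  0.1%, and with a literal discretized-`dA` rasterization oracle to 1% on
  random nested star-shaped sections — two independent routes to the same
  integrals.
- Full-pipeline values on decimated 20,000-face phantoms agree with the
  generator's closed forms to better than 1% (typically 0.05%).
- Tensor identities hold on every computed section: `J = Ix + Iy` exactly,
  `Imin + Imax = Ix + Iy`, rotation by −θ drives `|Ixy|` below
  `10⁻⁶·Imax`, and all reported properties are invariant under rigid
  pre-transforms of the specimen.
- A simulated 15 + 15 cohort constructed with CA ratio 0.70 is recovered
  within [67, 73]% with significance at every headline level, while
  periosteal-perimeter comparisons stay non-significant — the expansion
  mode changes the cavity, not the outer envelope.
- A regional-thinning cohort localizes its largest healthy-minus-osteo
  thickness differences to the anterior and lateral sectors of the
  20–45% BL band, by construction of the weight — this validates the
  mapping machinery, not any anatomical claim.

No empirical number appears in this vignette that the test suite or
`scripts/acceptance.R` does not itself compute.

## Known limitations

- Cleaning rejects rather than repairs non-manifold topology and does not
  detect self-intersections.
- Chord lengths are taken over contour polygon vertices, not a dense
  resampling; at 20,000 faces the vertex density bounds this error and the
  tests measure it.
- θ-dependent quantities are ill-conditioned for nearly circular sections
  (see above).
- The cadaveric cohort that motivated the pipeline is not deposited, so
  cohort-level agreement with published group ratios can only be assessed
  qualitatively through the synthetic stand-in, never numerically.
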